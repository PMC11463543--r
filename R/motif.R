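#' Hydrophobic residue set
#'
#' The Phi alphabet used by both sorting-motif grammars. The default is the
#' eight-residue Kyte-Doolittle-positive set; it is exposed as a parameter
#' because "hydrophobic" has no single canonical definition.
#'
#' @return character vector of one-letter residue codes.
#' @export
hydrophobic_set <- function() c("A", "V", "L", "I", "M", "F", "W", "Y")

#' Scan a sequence for a C-terminal SNX27 PDZ-binding motif
#'
#' The SNX27 PDZ domain recognizes C-terminal [S/T]-x-Phi motifs: serine or
#' threonine at the -3 position and a hydrophobic residue as the final
#' residue. At most one hit per protein is possible. The count of acidic
#' residues (D/E) in positions -4..-8 (clipped at the sequence start) is
#' reported as context — acidity upstream of the core motif enhances PDZ
#' binding — but never used as a filter.
#'
#' @param seq amino-acid string.
#' @param id protein identifier for the hit record.
#' @param phi hydrophobic residue set.
#' @return one-row data.frame (protein, motif_type, start, end, matched,
#'   c_terminal, acidic_context) or NULL when there is no hit.
#' @export
scan_snx27 <- function(seq, id = "query", phi = hydrophobic_set()) {
  n <- nchar(seq)
  if (n < 3L) {
    log_stage("scan", "sequence ", id, " shorter than 3 residues; skipped")
    return(NULL)
  }
  tail3 <- strsplit(substr(seq, n - 2L, n), "")[[1]]
  if (!(tail3[1] %in% c("S", "T")) || !(tail3[3] %in% phi)) return(NULL)
  ctx_start <- max(1L, n - 7L)
  ctx <- strsplit(substr(seq, ctx_start, n - 3L), "")[[1]]
  data.frame(protein = id, motif_type = "SNX27",
             start = n - 2L, end = n,
             matched = paste(tail3, collapse = ""),
             c_terminal = TRUE,
             acidic_context = sum(ctx %in% c("D", "E")),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for SNX17 FERM-binding motifs
#'
#' Finds every start position of the Phi-x-N-x-x-[Y/F] grammar (overlapping
#' windows allowed, one match per start). With \code{region =
#' "cytosolic_tail"} and a topology, the scan is restricted to residues
#' after the last transmembrane span; without topology it falls back to the
#' full sequence with a warning.
#'
#' @param seq amino-acid string.
#' @param id protein identifier.
#' @param region "full" or "cytosolic_tail".
#' @param topology optional list/data.frame of TM spans with \code{start}
#'   and \code{end} (1-based inclusive).
#' @param phi hydrophobic residue set.
#' @return data.frame of hits (possibly 0 rows): protein, motif_type,
#'   start, end, matched, c_terminal, region_flag.
#' @export
scan_snx17 <- function(seq, id = "query", region = c("full",
                                                     "cytosolic_tail"),
                       topology = NULL, phi = hydrophobic_set()) {
  region <- match.arg(region)
  empty <- data.frame(protein = character(0), motif_type = character(0),
                      start = integer(0), end = integer(0),
                      matched = character(0), c_terminal = logical(0),
                      region_flag = character(0), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < 6L) return(empty)
  offset <- 0L
  region_flag <- region
  if (region == "cytosolic_tail") {
    if (is.null(topology) || length(topology$end) == 0L) {
      warning("no topology for ", id, "; scanning full sequence")
      region_flag <- "full_fallback"
    } else {
      offset <- max(topology$end)
      if (offset >= n - 5L) return(empty)
      seq <- substr(seq, offset + 1L, n)
    }
  }
  pattern <- paste0("(?=([", paste(phi, collapse = ""), "].N..[YF]))")
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) + offset
  data.frame(protein = id, motif_type = "SNX17",
             start = starts, end = starts + 5L,
             matched = substring(seq, starts - offset, starts - offset + 5L),
             c_terminal = FALSE, region_flag = region_flag,
             stringsAsFactors = FALSE)
}

#' Scan many sequences for both sorting-motif types
#'
#' @param seqs named character vector of sequences.
#' @param motifs motif types to scan ("SNX27", "SNX17").
#' @param ... passed to the individual scanners.
#' @return data.frame of hits from [scan_snx27()] and [scan_snx17()]
#'   (columns unioned; SNX27 rows carry acidic_context, SNX17 rows
#'   region_flag).
#' @export
scan_motifs <- function(seqs, motifs = c("SNX27", "SNX17"), ...) {
  hits <- list()
  for (id in names(seqs)) {
    if ("SNX27" %in% motifs) {
      h <- scan_snx27(seqs[[id]], id = id)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
    if ("SNX17" %in% motifs) {
      h <- scan_snx17(seqs[[id]], id = id, ...)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits))
    return(data.frame(protein = character(0), motif_type = character(0),
                      start = integer(0), end = integer(0),
                      matched = character(0), c_terminal = logical(0),
                      stringsAsFactors = FALSE))
  cols <- Reduce(union, lapply(hits, names))
  hits <- lapply(hits, function(h) {
    h[setdiff(cols, names(h))] <- NA
    h[cols]
  })
  do.call(rbind, hits)
}

#' Extract peptide query windows around motif hits
#'
#' SNX27 queries are the exact C-terminal suffix of length min(15, protein
#' length) — the window screened against the PDZ domain. SNX17 queries are
#' 15-mers laid 4 residues upstream + motif + 5 downstream, shifted inward
#' at the termini so the 6-residue motif is always fully contained.
#'
#' @param hits data.frame of motif hits.
#' @param seqs named character vector of sequences.
#' @param role query role label, "candidate" or "control".
#' @return data.frame of class \code{peptide_query}: protein, motif_type,
#'   peptide, win_start, win_end, role, short (TRUE when the protein is
#'   shorter than the nominal window).
#' @export
extract_peptides <- function(hits, seqs, role = "candidate") {
  out <- lapply(seq_len(nrow(hits)), function(i) {
    id <- hits$protein[i]
    if (!id %in% names(seqs)) stop("hit protein absent from sequences: ", id)
    s <- seqs[[id]]
    n <- nchar(s)
    if (hits$start[i] < 1L || hits$end[i] > n)
      stop("hit coordinates out of bounds for ", id, " (corrupt input)")
    if (hits$motif_type[i] == "SNX27") {
      ws <- max(1L, n - 14L)
      we <- n
    } else {
      ws <- hits$start[i] - 4L
      we <- hits$end[i] + 5L
      if (ws < 1L) { we <- min(n, we + (1L - ws)); ws <- 1L }
      if (we > n) { ws <- max(1L, ws - (we - n)); we <- n }
    }
    data.frame(protein = id, motif_type = hits$motif_type[i],
               peptide = substr(s, ws, we), win_start = ws, win_end = we,
               role = role, short = (we - ws + 1L) < 15L,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(protein = character(0), motif_type = character(0),
               peptide = character(0), win_start = integer(0),
               win_end = integer(0), role = character(0), short = logical(0),
               stringsAsFactors = FALSE)
  class(res) <- c("peptide_query", "data.frame")
  res
}

#' Build candidate and control screening sets
#'
#' SNX27 candidates are the C-terminal windows of proteins with an SNX27
#' hit; SNX27 controls are the C-terminal windows of proteins that carry an
#' SNX17 hit but no SNX27 hit (mirroring the use of SNX17-only cargo as
#' negative controls for the PDZ screen). SNX17 candidates are every SNX17
#' motif window.
#'
#' @param snx27_hits,snx17_hits hit tables over the same cargo universe.
#' @param seqs named character vector of sequences.
#' @return list with \code{snx27} and \code{snx17}, each a
#'   \code{peptide_query} data.frame with candidate/control roles set.
#' @export
build_screen_sets <- function(snx27_hits, snx17_hits, seqs) {
  p27 <- unique(snx27_hits$protein)
  p17 <- unique(snx17_hits$protein)
  if (length(p27) == 0L && length(p17) == 0L)
    warning("no motif hits: empty screening sets")
  ctrl_prot <- setdiff(p17, p27)
  ctrl_hits <- data.frame(protein = ctrl_prot,
                          motif_type = rep("SNX27", length(ctrl_prot)),
                          start = pmax(1L, nchar(seqs[ctrl_prot]) - 2L),
                          end = nchar(seqs[ctrl_prot]),
                          stringsAsFactors = FALSE)
  snx27 <- rbind(
    extract_peptides(snx27_hits, seqs, role = "candidate"),
    extract_peptides(ctrl_hits, seqs, role = "control"))
  snx17 <- extract_peptides(snx17_hits, seqs, role = "candidate")
  list(snx27 = snx27, snx17 = snx17)
}

#' Deterministic mock complex-prediction scorer
#'
#' Test double for an external structure predictor: planted-motif queries
#' score Normal(0.8, 0.1), background queries Normal(0.3, 0.1), clamped to
#' [0, 1]. Scores are deterministic per (query, seed) via a hashed
#' substream, so the same query always receives the same score.
#'
#' @param queries \code{peptide_query} data.frame.
#' @param truth motif truth table from [simulate_sequences()] (its
#'   \code{planted} column marks deliberately planted motifs).
#' @param seed integer seed.
#' @param mu_planted,mu_background,sd score distribution parameters.
#' @return numeric vector of ipTM scores aligned with \code{queries}.
#' @export
mock_predictor <- function(queries, truth, seed = 1L, mu_planted = 0.8,
                           mu_background = 0.3, sd = 0.1) {
  planted_key <- unique(paste(truth$protein[truth$planted],
                              truth$motif_type[truth$planted]))
  vapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    is_planted <- q$role == "candidate" &&
      paste(q$protein, q$motif_type) %in% planted_key
    mu <- if (is_planted) mu_planted else mu_background
    s <- substream_seed(seed, paste("mock", q$protein, q$motif_type,
                                    q$peptide, sep = "|"))
    withr::with_seed(s, min(1, max(0, stats::rnorm(1, mu, sd))))
  }, 0)
}

#' Ingest externally computed complex-prediction scores
#'
#' @param path TSV with columns protein, peptide, motif_type, iptm.
#' @return score data.frame usable by [run_screen()].
#' @export
read_score_table <- function(path) {
  df <- read_table(path)
  need <- c("protein", "peptide", "motif_type", "iptm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Run the ipTM screen over peptide queries
#'
#' Attaches a score to every query — from an ingested score table or from a
#' scoring function — and applies the strict threshold: a query passes only
#' when iptm > cutoff. Queries missing from an ingested table get a missing
#' score and are excluded from the counts. Per-protein summaries use the
#' best window (a protein passes if any of its windows passes).
#'
#' @param queries \code{peptide_query} data.frame.
#' @param scores either a numeric vector aligned with queries, a score
#'   data.frame from [read_score_table()], or a function(queries) ->
#'   numeric.
#' @param cfg a [run_config()] (supplies \code{iptm_cutoff}).
#' @return list of class \code{screen_result}: \code{results} (queries +
#'   iptm + passed), \code{summary} (motif/protein-level pass counts by
#'   role) and \code{per_protein} (best score and pass per protein/role).
#' @export
run_screen <- function(queries, scores, cfg = run_config()) {
  iptm <- if (is.function(scores)) {
    scores(queries)
  } else if (is.data.frame(scores)) {
    key <- paste(scores$protein, scores$peptide, scores$motif_type,
                 sep = "|")
    qkey <- paste(queries$protein, queries$peptide, queries$motif_type,
                  sep = "|")
    got <- scores$iptm[match(qkey, key)]
    if (anyNA(got))
      log_stage("screen", sum(is.na(got)),
                " quer(ies) missing from the score table; excluded")
    got
  } else {
    stopifnot(is.numeric(scores), length(scores) == nrow(queries))
    scores
  }
  res <- queries
  res$iptm <- iptm
  res$passed <- !is.na(iptm) & iptm > cfg$iptm_cutoff
  scored <- res[!is.na(res$iptm), , drop = FALSE]
  per_protein <- do.call(rbind, lapply(
    split(scored, paste(scored$protein, scored$motif_type, scored$role,
                        sep = "|")),
    function(d) data.frame(protein = d$protein[1],
                           motif_type = d$motif_type[1], role = d$role[1],
                           best_iptm = max(d$iptm), passed = any(d$passed),
                           n_windows = nrow(d), stringsAsFactors = FALSE)))
  if (is.null(per_protein))
    per_protein <- data.frame(protein = character(0),
                              motif_type = character(0), role = character(0),
                              best_iptm = numeric(0), passed = logical(0),
                              n_windows = integer(0))
  rownames(per_protein) <- NULL
  per_protein <- per_protein[order(per_protein$motif_type, per_protein$role,
                                   per_protein$protein), , drop = FALSE]
  summarize <- function(d, pp) {
    c(queries = nrow(d), queries_passed = sum(d$passed),
      proteins = nrow(pp), proteins_passed = sum(pp$passed))
  }
  groups <- unique(scored[c("motif_type", "role")])
  summary <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    d <- scored[scored$motif_type == g$motif_type & scored$role == g$role, ]
    pp <- per_protein[per_protein$motif_type == g$motif_type &
                        per_protein$role == g$role, ]
    data.frame(motif_type = g$motif_type, role = g$role,
               t(summarize(d, pp)), stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(motif_type = character(0), role = character(0),
                          queries = integer(0), queries_passed = integer(0),
                          proteins = integer(0), proteins_passed = integer(0))
  structure(list(results = res, summary = summary,
                 per_protein = per_protein, iptm_cutoff = cfg$iptm_cutoff),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result (ipTM >", x$iptm_cutoff, "):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select top/bottom queries by ipTM rank
#'
#' Ties are broken by protein identifier so the selection is deterministic.
#'
#' @param screen a \code{screen_result}.
#' @param n_top,n_bottom how many highest/lowest scoring queries to take.
#' @param motif_type restrict to one motif type.
#' @param role restrict to one role, or NULL (default) to rank the whole
#'   screened pool, candidates and controls together.
#' @return list with \code{top} and \code{bottom} query data.frames.
#' @export
top_bottom_queries <- function(screen, n_top = 10L, n_bottom = 10L,
                               motif_type = "SNX27", role = NULL) {
  d <- screen$results
  d <- d[!is.na(d$iptm) & d$motif_type == motif_type, , drop = FALSE]
  if (!is.null(role)) d <- d[d$role == role, , drop = FALSE]
  desc <- d[order(-d$iptm, d$protein), , drop = FALSE]
  asc <- d[order(d$iptm, d$protein), , drop = FALSE]
  list(top = utils::head(desc, n_top), bottom = utils::head(asc, n_bottom))
}

#' Position frequency matrix and information content for a motif logo
#'
#' Aligned peptides (equal length; SNX27 windows right-aligned with "-"
#' padding for short peptides, gaps excluded from the counts) are turned
#' into per-position residue probabilities with pseudocounts, and the
#' information content IC_j = log2(20) - H_j in bits against a uniform
#' background.
#'
#' @param peptides character vector of aligned peptides.
#' @param pseudocount added to every residue count at every position
#'   (default 0.5).
#' @return list of class \code{pfm}: \code{probs} (20 x L matrix),
#'   \code{ic} (bits per position), \code{n_sequences},
#'   \code{pseudocount}.
#' @export
build_logo <- function(peptides, pseudocount = 0.5) {
  if (!length(peptides)) stop("no peptides")
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L)
    stop("peptides must be aligned to equal length (use pad_right_align())")
  L <- lens[1]
  aa <- amino_acids()
  chars <- do.call(rbind, strsplit(peptides, ""))
  probs <- matrix(NA_real_, nrow = 20L, ncol = L,
                  dimnames = list(aa, seq_len(L)))
  ic <- numeric(L)
  for (j in seq_len(L)) {
    col <- chars[, j]
    col <- col[col %in% aa]
    counts <- table(factor(col, levels = aa))
    pr <- (as.numeric(counts) + pseudocount) /
      (length(col) + 20 * pseudocount)
    probs[, j] <- pr
    h <- -sum(ifelse(pr > 0, pr * log2(pr), 0))
    ic[j] <- log2(20) - h
  }
  structure(list(probs = probs, ic = ic, n_sequences = length(peptides),
                 pseudocount = pseudocount), class = "pfm")
}

#' Right-align peptides to a common length with gap padding
#'
#' Pads shorter peptides on the left with "-" (excluded from logo counts),
#' the alignment used for C-terminal SNX27 windows.
#'
#' @param peptides character vector.
#' @param width target width (default: longest peptide).
#' @return character vector of equal-width strings.
#' @export
pad_right_align <- function(peptides, width = max(nchar(peptides))) {
  vapply(peptides, function(p)
    paste0(strrep("-", width - nchar(p)), p), "", USE.NAMES = FALSE)
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm:", ncol(x$probs), "positions over", x$n_sequences,
      "sequences; IC (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}
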