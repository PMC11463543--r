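#' Select candidate endocytic cargo
#'
#' Applies the cargo rule to an enriched protein set: a candidate is
#' enriched, carries at least one transmembrane segment, and is annotated
#' as localized in the cell membrane. Counts are also computed against the
#' supplied proteome universe and against a synaptic gene set when given.
#'
#' @param enriched character vector of enriched proteins.
#' @param a annotation data.frame with \code{protein}, \code{tm_count} and
#'   \code{cell_membrane} columns.
#' @param universe optional proteome universe (default: all annotated
#'   proteins) against which the PM/TM counts are taken.
#' @param synaptic_set optional character vector of synaptic proteins.
#' @return list of class \code{cargo_call_set}: \code{candidates},
#'   \code{unclassifiable} (enriched but unannotated), \code{counts}
#'   (pm_universe, pm_in_ip, syngo_pm_universe, syngo_pm_in_ip) and
#'   \code{fractions} (percent, unrounded and rounded).
#' @export
select_candidate_cargo <- function(enriched, a, universe = a$protein,
                                   synaptic_set = NULL) {
  enriched <- unique(enriched)
  unclass <- setdiff(enriched, a$protein)
  if (length(unclass))
    log_stage("cargo", length(unclass),
              " enriched protein(s) lack annotations (unclassifiable)")
  idx <- match(enriched, a$protein)
  eligible <- !is.na(idx) & a$tm_count[idx] >= 1L & a$cell_membrane[idx]
  candidates <- sort(enriched[eligible])

  pm_all <- a$protein[a$tm_count >= 1L & a$cell_membrane]
  pm_universe <- intersect(pm_all, universe)
  pm_in_ip <- intersect(pm_universe, enriched)
  counts <- c(pm_universe = length(pm_universe),
              pm_in_ip = length(pm_in_ip))
  fractions <- list(pm = cargo_fraction(length(pm_in_ip),
                                        max(length(pm_universe), 1L)))
  if (!is.null(synaptic_set)) {
    syn_pm <- intersect(pm_universe, synaptic_set)
    syn_in <- intersect(syn_pm, enriched)
    counts <- c(counts, syngo_pm_universe = length(syn_pm),
                syngo_pm_in_ip = length(syn_in))
    fractions$syngo <- if (length(syn_pm))
      cargo_fraction(length(syn_in), length(syn_pm)) else NULL
  }
  structure(list(candidates = candidates, unclassifiable = sort(unclass),
                 counts = counts, fractions = fractions),
            class = "cargo_call_set")
}

#' @export
print.cargo_call_set <- function(x, ...) {
  cat("cargo_call_set:", length(x$candidates), "candidates;",
      "PM/TM in IP:", x$counts["pm_in_ip"], "/", x$counts["pm_universe"],
      sprintf("(%.1f%%)", x$fractions$pm$percent), "\n")
  invisible(x)
}

#' Cargo fraction as a percentage
#'
#' The share of a plasma-membrane protein universe captured by the IP,
#' reported both unrounded and rounded half-up to the integer percent used
#' for headline reporting.
#'
#' @param in_ip count captured in the IP.
#' @param universe universe count (> 0, >= in_ip).
#' @return list with \code{percent} (exact), \code{percent_1dp} and
#'   \code{percent_rounded} (half-up integer).
#' @export
cargo_fraction <- function(in_ip, universe) {
  if (universe <= 0) stop("universe count must be > 0")
  if (in_ip > universe) stop("in_ip exceeds universe")
  pct <- 100 * in_ip / universe
  list(percent = pct, percent_1dp = round(pct, 1),
       percent_rounded = floor(pct + 0.5))
}

#' Domain/family presence matrix for candidate cargo
#'
#' Binary candidate-by-annotation matrix over every domain and family name
#' seen among the candidates, with rows grouped by family then sorted by
#' identifier, plus the partition of candidates into those holding both a
#' domain and a family annotation, exactly one, or neither.
#'
#' @param candidates character vector of candidate proteins.
#' @param a annotation data.frame with semicolon-separated \code{domains}
#'   and \code{families} columns (and optionally \code{gene_sets} for the
#'   synaptic flag).
#' @param synaptic_set_name gene-set name flagged per row (default
#'   "synaptic").
#' @return list with \code{matrix} (binary, candidates x labels),
#'   \code{categories} (named counts: both, one, neither) and
#'   \code{table} (per-candidate: domains, families, category, synaptic).
#' @export
domain_family_matrix <- function(candidates, a,
                                 synaptic_set_name = "synaptic") {
  idx <- match(candidates, a$protein)
  doms <- split_labels(a$domains[idx])
  fams <- split_labels(a$families[idx])
  gsets <- if ("gene_sets" %in% names(a)) split_labels(a$gene_sets[idx])
           else rep(list(character(0)), length(candidates))
  has_d <- lengths(doms) > 0L
  has_f <- lengths(fams) > 0L
  category <- ifelse(has_d & has_f, "both",
                     ifelse(has_d | has_f, "one", "neither"))
  tab <- data.frame(protein = candidates,
                    domains = join_labels(doms), families = join_labels(fams),
                    category = category,
                    synaptic = vapply(gsets, function(s)
                      synaptic_set_name %in% s, TRUE),
                    stringsAsFactors = FALSE)
  # group by (first) family, then protein id
  fam1 <- vapply(fams, function(f) if (length(f)) sort(f)[1] else "~none", "")
  tab <- tab[order(fam1, tab$protein), , drop = FALSE]
  labels <- sort(unique(c(unlist(doms), unlist(fams))))
  m <- matrix(0L, nrow = nrow(tab), ncol = length(labels),
              dimnames = list(tab$protein, labels))
  for (i in seq_len(nrow(tab))) {
    hit <- c(doms[[match(tab$protein[i], candidates)]],
             fams[[match(tab$protein[i], candidates)]])
    m[i, match(hit, labels)] <- 1L
  }
  list(matrix = m,
       categories = c(both = sum(category == "both"),
                      one = sum(category == "one"),
                      neither = sum(category == "neither")),
       table = tab)
}
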