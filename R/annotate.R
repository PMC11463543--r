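#' Per-compartment distribution of log2 fold changes
#'
#' Joins compartment labels onto an enrichment table and summarizes the
#' log2FC distribution per compartment (count, mean, quartiles). Proteins
#' carrying several compartment labels contribute to each of them.
#'
#' @param e an \code{enrichment_table}.
#' @param a annotation data.frame with \code{protein} and a
#'   semicolon-separated \code{compartments} column.
#' @return data.frame: compartment, n, mean_log2FC, q1, median, q3.
#' @export
compartment_summary <- function(e, a) {
  comp <- split_labels(a$compartments[match(e$protein, a$protein)])
  rows <- rep(seq_len(nrow(e)), lengths(comp))
  long <- data.frame(compartment = unlist(comp),
                     log2FC = e$log2FC[rows], stringsAsFactors = FALSE)
  long <- long[is.finite(long$log2FC), , drop = FALSE]
  out <- do.call(rbind, lapply(split(long$log2FC, long$compartment),
    function(x) {
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(n = length(x), mean_log2FC = mean(x),
                 q1 = qs[1], median = qs[2], q3 = qs[3])
    }))
  out <- data.frame(compartment = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$compartment), , drop = FALSE]
}

#' Disjoint-region overlap report for 2-3 protein sets
#'
#' Computes every Venn region (counts and member lists) for two or three
#' named sets, as used to compare Endo-IP vs Lyso-IP enriched proteins and
#' hESC vs iNeuron identifications.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return list with \code{counts} (named integer vector over disjoint
#'   regions, e.g. "A_only", "A_and_B") and \code{members} (the
#'   corresponding identifier lists).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 sets")
  if (length(sets) > 3L)
    stop("overlap report restricted to 2-3 sets, got ", length(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  names(patterns) <- names(sets)
  members <- list()
  for (i in seq_len(nrow(patterns))) {
    inn <- unlist(patterns[i, ])
    hit <- rep(TRUE, length(universe))
    for (j in seq_along(sets)) hit <- hit & (member[, j] == inn[j])
    region <- paste0(paste(names(sets)[inn], collapse = "_and_"),
                     if (sum(inn) == 1L) "_only" else "")
    members[[region]] <- universe[hit]
  }
  list(counts = vapply(members, length, 1L), members = members)
}

#' Classify state selectivity of proteins by abundance ratio
#'
#' Bins each protein of a state-selective set by its log2 abundance ratio
#' between two cell states: higher (ratio >= tau), lower (ratio <= -tau),
#' else equal. Proteins without a ratio fall into an "unquantified" bin;
#' proportions are reported over the quantified proteins.
#'
#' @param selective character vector of selective proteins (non-empty).
#' @param abundance_ratio named numeric vector of log2 state ratios.
#' @param tau log2 threshold (default 1.0).
#' @return list with \code{proportions} (higher, equal, lower; sums to 1),
#'   \code{counts} (including unquantified) and \code{n_quantified}.
#' @export
classify_state_selectivity <- function(selective, abundance_ratio,
                                       tau = 1.0) {
  if (length(selective) == 0L) stop("empty selective set")
  r <- abundance_ratio[match(selective, names(abundance_ratio))]
  quant <- !is.na(r)
  if (mean(quant) < 0.8)
    warning("ratios available for < 80% of the selective set")
  rq <- r[quant]
  counts <- c(higher = sum(rq >= tau), equal = sum(abs(rq) < tau),
              lower = sum(rq <= -tau), unquantified = sum(!quant))
  props <- counts[c("higher", "equal", "lower")] / sum(quant)
  list(proportions = props, counts = counts, n_quantified = sum(quant))
}

#' Hypergeometric gene-set over-representation test
#'
#' For each set, tests over-representation of the foreground in the set
#' against the supplied universe: p = P[X >= k] for X ~
#' Hypergeometric(N, K, n), with BH adjustment across all sets tested.
#'
#' @param fg foreground protein set (must be a subset of the universe).
#' @param universe background protein universe.
#' @param sets a \code{geneset_collection} or named list of protein sets
#'   (members outside the universe are ignored).
#' @return data.frame: set, k (overlap), K (set size in universe), n
#'   (foreground size), N (universe size), p, q.
#' @export
geneset_enrichment <- function(fg, universe, sets) {
  fg <- unique(fg)
  universe <- unique(universe)
  off <- setdiff(fg, universe)
  if (length(off))
    stop("foreground proteins outside the universe: ",
         paste(utils::head(off, 10), collapse = ", "))
  N <- length(universe)
  n <- length(fg)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, fg))
    K <- length(s)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res[order(res$p, res$set), , drop = FALSE]
}
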