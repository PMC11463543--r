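#' Log2-transform and median-centre an intensity matrix
#'
#' Intensities are log2-transformed (zeros and negative values having been
#' recorded as missing on input) and each channel is shifted so its median
#' equals the grand median of all channel medians. A constant per-channel
#' scale factor therefore cancels exactly; missingness is preserved.
#'
#' Median centering assumes most proteins are unchanged between tagged and
#' control channels. When a sizeable fraction is enriched, the tagged-channel
#' medians rise and centering shifts every fold change down by that amount;
#' \code{center = FALSE} gives the pure transform when an unbiased
#' fold-change scale is needed (e.g. against simulation ground truth).
#'
#' @param m an [intensity_matrix()] on the reporter scale.
#' @param center shift channels to the grand median (default TRUE).
#' @return an [intensity_matrix()] with \code{log2_scale = TRUE}.
#' @export
normalize_log2 <- function(m, center = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$log2_scale) stop("matrix is already on the log2 scale")
  v <- log2(m$values)
  n_finite <- colSums(is.finite(v))
  if (any(n_finite == 0L))
    stop("all-missing channel(s): ",
         paste(colnames(v)[n_finite == 0L], collapse = ", "))
  if (any(n_finite < 10L))
    warning("channel(s) with < 10 finite values: ",
            paste(colnames(v)[n_finite < 10L], collapse = ", "))
  if (center) {
    med <- apply(v, 2L, stats::median, na.rm = TRUE)
    v <- sweep(v, 2L, med - stats::median(med))
  }
  intensity_matrix(v, m$design, log2_scale = TRUE)
}

# Newton solver for trigamma(x) = y, vectorized; used by the moment-matched
# scaled-F prior fit
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

# per-protein pooled two-group residual variances on the log2 scale
group_stats <- function(m, stratum = NULL) {
  stopifnot(inherits(m, "intensity_matrix"), m$log2_scale)
  d <- m$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(stratum)) {
    if (!is.null(stratum$ip_type)) keep <- keep & d$ip_type == stratum$ip_type
    if (!is.null(stratum$cell_state))
      keep <- keep & d$cell_state == stratum$cell_state
  }
  if (!any(keep)) stop("empty stratum")
  v <- m$values[, keep, drop = FALSE]
  cond <- d$condition[keep]
  vt <- v[, cond == "tagged", drop = FALSE]
  vc <- v[, cond == "control", drop = FALSE]
  n_t <- rowSums(is.finite(vt))
  n_c <- rowSums(is.finite(vc))
  mean_t <- rowMeans(vt, na.rm = TRUE)
  mean_c <- rowMeans(vc, na.rm = TRUE)
  ss <- function(x, mu, n) {
    out <- rowSums((x - mu)^2, na.rm = TRUE)
    out[n == 0L] <- NA_real_
    out
  }
  df <- pmax(n_t + n_c - 2L, 0L)
  s2 <- (ss(vt, mean_t, n_t) + ss(vc, mean_c, n_c)) / ifelse(df > 0, df, NA)
  data.frame(protein = rownames(v), n_tagged = n_t, n_control = n_c,
             log2FC = mean_t - mean_c, s2 = s2, df = df,
             stringsAsFactors = FALSE)
}

#' Fit the empirical-Bayes variance prior
#'
#' Pools information across proteins by fitting a scaled-F prior to the
#' per-protein pooled two-group residual variances: on the log scale,
#' \eqn{E[\log s^2_g]} and \eqn{Var[\log s^2_g]} have closed forms in the
#' digamma/trigamma functions, and the prior degrees of freedom d0 and prior
#' variance s0^2 are recovered by moment matching (Newton inversion of the
#' trigamma identity). Proteins with zero residual degrees of freedom are
#' excluded from the fit.
#'
#' @param m a log2-scale [intensity_matrix()].
#' @param stratum optional list(ip_type =, cell_state =) restricting the
#'   channels used.
#' @return an object of class \code{ebayes_model} with elements \code{d0}
#'   (prior df; \code{Inf} when the observed variances show no
#'   extra-sampling spread) and \code{s0_sq}.
#' @export
fit_ebayes <- function(m, stratum = NULL) {
  gs <- group_stats(m, stratum)
  usable <- gs$df > 0 & is.finite(gs$s2) & gs$s2 > 0
  if (sum(usable) < 20L) {
    warning("fewer than 20 usable proteins; falling back to d0 = Inf with ",
            "s0_sq = median(s2)")
    s0 <- stats::median(gs$s2[usable])
    if (!is.finite(s0)) stop("no usable residual variances")
    return(structure(list(d0 = Inf, s0_sq = s0), class = "ebayes_model"))
  }
  s2 <- gs$s2[usable]
  dg <- gs$df[usable]
  z <- log(s2)
  if (stats::var(z) < 1e-12) {
    # observed variances carry no spread at all: the prior is a point mass
    # at the common variance
    return(structure(list(d0 = Inf, s0_sq = exp(mean(z))),
                     class = "ebayes_model"))
  }
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dg / 2))
  if (is.na(evar) || evar <= 1e-8) {
    d0 <- Inf
    s0 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0), class = "ebayes_model")
}

#' Construct an empirical-Bayes variance model directly
#'
#' Useful for the limiting cases: d0 = 0 gives the ordinary two-sample t,
#' d0 = Inf fixes the variance at s0_sq.
#'
#' @param d0 prior degrees of freedom, >= 0 (may be \code{Inf}).
#' @param s0_sq prior variance, > 0 (log2 units squared).
#' @return an \code{ebayes_model}.
#' @export
ebayes_model <- function(d0, s0_sq) {
  stopifnot(d0 >= 0, s0_sq > 0)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_model")
}

#' @export
print.ebayes_model <- function(x, ...) {
  cat("ebayes_model: d0 =", x$d0, "| s0_sq =", x$s0_sq, "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up BH with monotonicity enforcement and stable tie order; missing
#' p-values propagate as missing and do not count toward the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return vector of q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0L) return(q)
  o <- ok[order(p[ok])]
  qq <- p[o] * n / seq_len(n)
  qq <- rev(cummin(rev(qq)))
  q[o] <- pmin(qq, 1)
  q
}

#' Moderated differential-enrichment test
#'
#' For each protein with at least two finite values per group: log2FC =
#' mean(tagged) - mean(control); posterior variance
#' \eqn{s^2_{post} = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}; moderated
#' statistic \eqn{t = log2FC / \sqrt{s^2_{post}(1/n_t + 1/n_c)}}; two-sided
#' p from the t distribution on \eqn{d_0 + d_g} df (normal when d0 is
#' infinite); q by BH over all tested proteins. A protein is called
#' enriched when log2FC >= \code{cfg$lfc_cutoff} and q <=
#' \code{cfg$q_cutoff}. Proteins with insufficient observations are
#' reported with missing statistics and enriched = FALSE.
#'
#' @param m a log2-scale [intensity_matrix()].
#' @param model an [fit_ebayes()] model (d0 = 0 reduces exactly to the
#'   ordinary pooled-variance two-sample t).
#' @param cfg a [run_config()] carrying the cutoffs.
#' @param stratum optional list(ip_type =, cell_state =).
#' @return data.frame of class \code{enrichment_table}: protein, log2FC,
#'   s2, t_mod, p, q, enriched, n_tagged, n_control.
#' @export
test_enrichment <- function(m, model, cfg = run_config(), stratum = NULL) {
  stopifnot(inherits(model, "ebayes_model"))
  gs <- group_stats(m, stratum)
  testable <- gs$n_tagged >= 2L & gs$n_control >= 2L & is.finite(gs$s2)
  d0 <- model$d0
  s0 <- model$s0_sq
  s2_post <- t_mod <- p <- rep(NA_real_, nrow(gs))
  idx <- which(testable)
  if (length(idx)) {
    dg <- gs$df[idx]
    s2_post[idx] <- if (is.infinite(d0)) s0 else
      (d0 * s0 + dg * gs$s2[idx]) / (d0 + dg)
    se <- sqrt(s2_post[idx] * (1 / gs$n_tagged[idx] + 1 / gs$n_control[idx]))
    t_mod[idx] <- gs$log2FC[idx] / se
    df_tot <- d0 + dg
    p[idx] <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_mod[idx])) else
      2 * stats::pt(-abs(t_mod[idx]), df = df_tot)
  }
  q <- bh_adjust(p)
  out <- data.frame(protein = gs$protein, log2FC = gs$log2FC, s2 = gs$s2,
                    t_mod = t_mod, p = p, q = q,
                    enriched = !is.na(q) & gs$log2FC >= cfg$lfc_cutoff &
                      q <= cfg$q_cutoff,
                    n_tagged = gs$n_tagged, n_control = gs$n_control,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Reproducibility report for two enrichment tables
#'
#' Compares two independently processed datasets: Jaccard index of the
#' enriched sets, Pearson correlation of log2 fold changes over shared
#' proteins, and the overlap counts.
#'
#' @param a,b \code{enrichment_table}s.
#' @return list with \code{jaccard}, \code{pearson_r}, and \code{counts}
#'   (n_a, n_b, shared, enriched_a, enriched_b, enriched_both).
#' @export
compare_replicate_datasets <- function(a, b) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  shared <- intersect(a$protein, b$protein)
  ea <- a$protein[a$enriched]
  eb <- b$protein[b$enriched]
  uni <- union(ea, eb)
  jac <- if (length(uni)) length(intersect(ea, eb)) / length(uni) else 0
  r <- NA_real_
  if (length(shared) == 0L) {
    warning("no shared proteins between the two datasets")
    jac <- 0
  } else {
    fa <- a$log2FC[match(shared, a$protein)]
    fb <- b$log2FC[match(shared, b$protein)]
    ok <- is.finite(fa) & is.finite(fb)
    if (sum(ok) >= 3L && stats::sd(fa[ok]) > 0 && stats::sd(fb[ok]) > 0) {
      r <- stats::cor(fa[ok], fb[ok])
    } else {
      warning("log2FC correlation undefined on shared proteins")
    }
  }
  list(jaccard = jac, pearson_r = r,
       counts = c(n_a = nrow(a), n_b = nrow(b), shared = length(shared),
                  enriched_a = length(ea), enriched_b = length(eb),
                  enriched_both = length(intersect(ea, eb))))
}
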