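# shared in-code fixtures

# minimal one-stratum triplicate design
tiny_design <- function(ip_type = "endo", cell_state = "iNeuron", r = 3L) {
  design_table(
    channel_id = c(sprintf("tag_%d", seq_len(r)),
                   sprintf("ctl_%d", seq_len(r))),
    condition = rep(c("tagged", "control"), each = r),
    ip_type = ip_type, cell_state = cell_state,
    replicate = rep(seq_len(r), 2L))
}

# intensity matrix with given per-protein log2 means for tagged/control
tiny_matrix <- function(log2_tagged, log2_control, design = tiny_design(),
                        proteins = sprintf("P%03d", seq_along(log2_tagged))) {
  r <- sum(design$condition == "tagged")
  v <- cbind(matrix(rep(log2_tagged, r), ncol = r),
             matrix(rep(log2_control, r), ncol = r))
  dimnames(v) <- list(proteins, design$channel_id)
  intensity_matrix(2^v, design)
}

# brute-force O(n^2) Benjamini-Hochberg: q_i = min over {j : p_j >= p_i}
# of p_j * n / rank(p_j), computed directly from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  r <- integer(n)
  r[o] <- seq_len(n)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(vapply(seq_len(n)[p >= p[i] - 1e-15], function(j)
      p[j] * n / r[j], 0), 1)
  }
  q
}

# exhaustive hypergeometric over-representation p-value: enumerate every
# size-n draw from the universe and count those with >= k set members
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- draws <= K  # first K elements form the set
  mean(colSums(in_set) >= k)
}

# position-by-position motif checkers, independent of the scanners
snx27_oracle <- function(s, phi = c("A","V","L","I","M","F","W","Y")) {
  n <- nchar(s)
  if (n < 3) return(FALSE)
  ch <- strsplit(s, "")[[1]]
  ch[n - 2] %in% c("S", "T") && ch[n] %in% phi
}
snx17_oracle_starts <- function(s,
                                phi = c("A","V","L","I","M","F","W","Y")) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 6) return(integer(0))
  which(vapply(seq_len(n - 5), function(i)
    ch[i] %in% phi && ch[i + 2] == "N" && ch[i + 5] %in% c("Y", "F"),
    TRUE))
}

random_aa_seq <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
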