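#' Simulation configuration
#'
#' Parameters of the synthetic organelle-IP experiment generator. Defaults
#' describe a triplicate tagged-vs-untagged IP with compartment-structured
#' enrichment effects and a single log-normal noise term.
#'
#' @param n_proteins number of simulated proteins.
#' @param fractions named probabilities over the compartment classes
#'   \code{lysosome, endosome, plasma_membrane, mitochondrion, ER, Golgi,
#'   cytosol}; must sum to 1.
#' @param enrichment_effect mean log2 enrichment of a protein in the IP
#'   targeting its home compartment (default 2.5).
#' @param core_effect log2 cross-capture enrichment of shared endolysosomal
#'   core proteins in the non-home IP (default 1.5).
#' @param core_prob probability that an endosomal or lysosomal protein
#'   belongs to the shared endolysosomal core (default 0.15).
#' @param pm_capture_prob probability that a plasma-membrane protein is
#'   endocytosed and hence captured by the Endo-IP (default 0.3).
#' @param noise_sd log2-scale measurement noise standard deviation
#'   (default 0.35).
#' @param replicates biological replicates per condition (>= 2).
#' @param missing_rate probability an intensity is masked missing, in
#'   [0, 0.5).
#' @param seed base RNG seed; every generator draws from a named substream
#'   of it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_proteins = 1000L,
                       fractions = c(lysosome = 0.08, endosome = 0.08,
                                     plasma_membrane = 0.14,
                                     mitochondrion = 0.12, ER = 0.12,
                                     Golgi = 0.06, cytosol = 0.40),
                       enrichment_effect = 2.5, core_effect = 1.5,
                       core_prob = 0.15, pm_capture_prob = 0.3,
                       noise_sd = 0.35, replicates = 3L,
                       missing_rate = 0.02, seed = 1L) {
  wanted <- c("lysosome", "endosome", "plasma_membrane", "mitochondrion",
              "ER", "Golgi", "cytosol")
  if (!setequal(names(fractions), wanted))
    stop("fractions must be named over: ", paste(wanted, collapse = ", "))
  fractions <- fractions[wanted]
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("compartment fractions must sum to 1 (got ", sum(fractions), ")")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("missing_rate must lie in [0, 0.5)")
  if (replicates < 2L) stop("replicates must be >= 2: statistics undefined")
  structure(list(n_proteins = as.integer(n_proteins), fractions = fractions,
                 enrichment_effect = enrichment_effect,
                 core_effect = core_effect, core_prob = core_prob,
                 pm_capture_prob = pm_capture_prob, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a tagged-vs-control organelle-IP experiment
#'
#' Per protein i and channel c, log2 intensity = baseline_i +
#' effect_i * [c tagged] + Normal(0, noise_sd), with baseline_i ~
#' Normal(20, 2) log2 units. effect_i is \code{enrichment_effect} for
#' proteins of the IP's target compartment (and for captured
#' plasma-membrane proteins in the Endo-IP), \code{core_effect} for shared
#' endolysosomal core proteins in the non-home IP, and 0 otherwise. Values
#' are returned on the intensity scale with entries masked missing at
#' \code{missing_rate}.
#'
#' @param cfg a [sim_config()].
#' @param ip_type "endo" or "lyso".
#' @param cell_state "hESC", "iNeuron" or "other".
#' @param noise_stream substream name for the measurement-noise draws; vary
#'   it to generate independent technical repeats of one biological truth.
#' @return list with elements \code{matrix} (an [intensity_matrix()]),
#'   \code{design} and \code{truth} (a \code{data.frame}: protein,
#'   compartment, core, captured, effect_endo, effect_lyso, baseline, with
#'   the config echoed in \code{attr(truth, "sim_config")}).
#' @export
simulate_ip_experiment <- function(cfg, ip_type = "endo",
                                   cell_state = "iNeuron",
                                   noise_stream = "ip_noise") {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))
  truth <- with_substream(cfg$seed, "ip_truth", {
    compartment <- sample(names(cfg$fractions), n, replace = TRUE,
                          prob = cfg$fractions)
    core <- compartment %in% c("lysosome", "endosome") &
      stats::runif(n) < cfg$core_prob
    captured <- compartment == "plasma_membrane" &
      stats::runif(n) < cfg$pm_capture_prob
    baseline <- stats::rnorm(n, mean = 20, sd = 2)
    # home IP carries the full effect; shared endolysosomal core proteins
    # cross-capture into the other IP; endocytosed PM proteins enter Endo-IP
    effect_endo <- numeric(n)
    effect_endo[compartment == "endosome"] <- cfg$enrichment_effect
    effect_endo[compartment == "lysosome" & core] <- cfg$core_effect
    effect_endo[captured] <- cfg$enrichment_effect
    effect_lyso <- numeric(n)
    effect_lyso[compartment == "lysosome"] <- cfg$enrichment_effect
    effect_lyso[compartment == "endosome" & core] <- cfg$core_effect
    data.frame(protein = proteins, compartment = compartment,
               core = core, captured = captured,
               effect_endo = effect_endo, effect_lyso = effect_lyso,
               baseline = baseline, stringsAsFactors = FALSE)
  })
  attr(truth, "sim_config") <- cfg

  r <- cfg$replicates
  design <- design_table(
    channel_id = c(sprintf("%s_%s_tag_%d", ip_type, cell_state, seq_len(r)),
                   sprintf("%s_%s_ctl_%d", ip_type, cell_state, seq_len(r))),
    condition = rep(c("tagged", "control"), each = r),
    ip_type = ip_type, cell_state = cell_state,
    replicate = rep(seq_len(r), 2L))

  effect <- if (ip_type == "endo") truth$effect_endo else truth$effect_lyso
  tagged <- design$condition == "tagged"
  vals <- with_substream(cfg$seed, paste0(noise_stream, ":", ip_type, ":",
                                          cell_state), {
    eps <- matrix(stats::rnorm(n * nrow(design), sd = cfg$noise_sd),
                  nrow = n)
    log2v <- truth$baseline + outer(effect, as.numeric(tagged)) + eps
    v <- 2^log2v
    if (cfg$missing_rate > 0) {
      v[stats::runif(length(v)) < cfg$missing_rate] <- NA_real_
    }
    v
  })
  dimnames(vals) <- list(proteins, design$channel_id)
  list(matrix = intensity_matrix(vals, design), design = design,
       truth = truth)
}

#' Simulate protein annotations matching a simulation truth
#'
#' Compartment labels are copied from truth; transmembrane counts are drawn
#' in 0..12 with cell-membrane proteins guaranteed at least one TM segment;
#' synthetic gene sets are assigned, including a "synaptic" set whose
#' membership is enriched among plasma-membrane proteins at a configurable
#' odds ratio.
#'
#' @param truth truth table from [simulate_ip_experiment()].
#' @param synaptic_or odds ratio of synaptic-set membership for
#'   plasma-membrane vs other proteins (1 = null).
#' @param base_set_rate baseline gene-set membership probability.
#' @param n_random_sets number of additional unstructured gene sets.
#' @param seed RNG seed (defaults to the truth's config seed).
#' @return list with \code{annotations} (data.frame: protein, compartments,
#'   tm_count, cell_membrane, gene_sets, domains, families) and \code{truth}
#'   with tm_count / cell_membrane columns appended.
#' @export
simulate_annotations <- function(truth, synaptic_or = 4, base_set_rate = 0.1,
                                 n_random_sets = 3L,
                                 seed = attr(truth, "sim_config")$seed) {
  n <- nrow(truth)
  pm <- truth$compartment == "plasma_membrane"
  ann <- with_substream(seed, "annotations", {
    tm <- sample(0:12, n, replace = TRUE,
                 prob = c(0.55, 0.18, 0.06, 0.04, 0.035, 0.025, 0.02, 0.055,
                          0.005, 0.005, 0.005, 0.005, 0.01))
    tm[pm & tm == 0L] <- sample(1:12, sum(pm & tm == 0L), replace = TRUE)
    # synaptic membership: odds base_set_rate/(1-base_set_rate), scaled by
    # synaptic_or for plasma-membrane proteins
    odds <- base_set_rate / (1 - base_set_rate)
    p_syn <- ifelse(pm, odds * synaptic_or / (1 + odds * synaptic_or),
                    base_set_rate)
    synaptic <- stats::runif(n) < p_syn
    sets <- lapply(seq_len(n), function(i) {
      s <- sprintf("set%02d", which(stats::runif(n_random_sets) <
                                      base_set_rate))
      if (synaptic[i]) s <- c("synaptic", s)
      s
    })
    domains <- ifelse(stats::runif(n) < 0.4,
                      sprintf("domain%02d", sample(1:12, n, replace = TRUE)),
                      "")
    families <- ifelse(stats::runif(n) < 0.4,
                       sprintf("family%02d", sample(1:10, n, replace = TRUE)),
                       "")
    data.frame(protein = truth$protein,
               compartments = truth$compartment,
               tm_count = tm,
               cell_membrane = pm,
               gene_sets = vapply(sets, paste, "", collapse = ";"),
               domains = domains, families = families,
               stringsAsFactors = FALSE)
  })
  truth$tm_count <- ann$tm_count
  truth$cell_membrane <- ann$cell_membrane
  list(annotations = ann, truth = truth)
}

amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Simulate protein sequences with planted sorting motifs
#'
#' Background residues are i.i.d. uniform over the 20-letter alphabet.
#' SNX27 motifs ([S/T]-x-Phi) are written onto the final three residues;
#' SNX17 motifs (Phi-x-N-x-x-[Y/F]) at a random internal position at least
#' 10 residues from either terminus. Accidental background matches are
#' detected post hoc with the package's own scanners and recorded in the
#' truth table (planted = FALSE), so scanner sensitivity and specificity can
#' be computed against complete truth.
#'
#' @param n number of sequences.
#' @param plant_snx27,plant_snx17 per-sequence planting probabilities.
#' @param length_range integer length bounds; the lower bound must be >= 16
#'   (>= 26 when SNX17 motifs are planted, so the internal-placement rule is
#'   satisfiable).
#' @param seed RNG seed.
#' @param ids optional sequence identifiers (default Q00001...).
#' @return list with \code{sequences} (named character vector) and
#'   \code{motifs} (data.frame: protein, motif_type, start, end, peptide,
#'   planted).
#' @export
simulate_sequences <- function(n, plant_snx27 = 0.5, plant_snx17 = 0.5,
                               length_range = c(60L, 300L), seed = 1L,
                               ids = NULL) {
  stopifnot(plant_snx27 >= 0, plant_snx27 <= 1,
            plant_snx17 >= 0, plant_snx17 <= 1)
  if (length_range[1] < 16L)
    stop("length_range lower bound must be >= 16: peptide windows undefined")
  if (plant_snx17 > 0 && length_range[1] < 26L)
    stop("length_range lower bound must be >= 26 to plant internal SNX17 ",
         "motifs >= 10 residues from each terminus")
  if (is.null(ids)) ids <- sprintf("Q%05d", seq_len(n))
  aa <- amino_acids()
  phi <- hydrophobic_set()
  res <- with_substream(seed, "sequences", {
    planted <- list()
    seqs <- character(n)
    for (i in seq_len(n)) {
      len <- length_range[1] +
        sample.int(length_range[2] - length_range[1] + 1L, 1L) - 1L
      s <- sample(aa, len, replace = TRUE)
      if (stats::runif(1) < plant_snx27) {
        s[len - 2L] <- sample(c("S", "T"), 1L)
        s[len - 1L] <- sample(aa, 1L)
        s[len] <- sample(phi, 1L)
        planted[[length(planted) + 1L]] <-
          data.frame(protein = ids[i], motif_type = "SNX27",
                     start = len - 2L, end = len,
                     peptide = paste(s[(len - 2L):len], collapse = ""),
                     planted = TRUE, stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < plant_snx17) {
        start <- sample(seq(11L, len - 15L), 1L)
        motif <- c(sample(phi, 1L), sample(aa, 1L), "N", sample(aa, 1L),
                   sample(aa, 1L), sample(c("Y", "F"), 1L))
        s[start:(start + 5L)] <- motif
        planted[[length(planted) + 1L]] <-
          data.frame(protein = ids[i], motif_type = "SNX17",
                     start = start, end = start + 5L,
                     peptide = paste(motif, collapse = ""),
                     planted = TRUE, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    list(seqs = stats::setNames(seqs, ids),
         planted = if (length(planted)) do.call(rbind, planted) else
           data.frame(protein = character(0), motif_type = character(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), planted = logical(0)))
  })
  motifs <- complete_motif_truth(res$seqs, res$planted)
  list(sequences = res$seqs, motifs = motifs)
}

# augment planted-motif records with accidental background matches found by
# the scanners, so the truth table covers every match present
complete_motif_truth <- function(seqs, planted) {
  found <- list()
  for (id in names(seqs)) {
    h27 <- scan_snx27(seqs[[id]], id = id)
    if (!is.null(h27))
      found[[length(found) + 1L]] <-
        data.frame(protein = id, motif_type = "SNX27", start = h27$start,
                   end = h27$end, peptide = h27$matched,
                   stringsAsFactors = FALSE)
    h17 <- scan_snx17(seqs[[id]], id = id)
    if (nrow(h17))
      found[[length(found) + 1L]] <-
        data.frame(protein = id, motif_type = "SNX17", start = h17$start,
                   end = h17$end, peptide = h17$matched,
                   stringsAsFactors = FALSE)
  }
  found <- if (length(found)) do.call(rbind, found) else
    planted[, c("protein", "motif_type", "start", "end", "peptide")]
  key <- function(d) paste(d$protein, d$motif_type, d$start, sep = "|")
  found$planted <- key(found) %in% key(planted)
  found[order(found$protein, found$motif_type, found$start), , drop = FALSE]
}

#' Built-in differentiation profile shapes
#'
#' Three canonical trajectory templates over normalized time t in [0, 1]:
#' monotone up, monotone down, and a transient mid-course peak.
#'
#' @return named list of functions of normalized time.
#' @export
default_cluster_shapes <- function() {
  list(up = function(t) t,
       down = function(t) 1 - t,
       transient = function(t) exp(-((t - 0.5) / 0.2)^2))
}

#' Simulate a differentiation time-course profile matrix
#'
#' Proteins are assigned cyclically to the supplied shape templates; each
#' profile is its shape evaluated at the sampling days plus Normal noise.
#'
#' @param n_proteins number of proteins.
#' @param days sampling days across the differentiation (default 0..12 in
#'   steps of 2).
#' @param cluster_shapes named list of >= 2 shape functions of normalized
#'   time in [0, 1] (see [default_cluster_shapes()]).
#' @param noise_sd Normal noise SD in units of the shape amplitude.
#' @param seed RNG seed.
#' @return list with \code{profiles} (proteins x days matrix) and
#'   \code{labels} (integer truth cluster per protein, named by shape).
#' @export
simulate_timecourse <- function(n_proteins = 300L,
                                days = seq(0, 12, by = 2),
                                cluster_shapes = default_cluster_shapes(),
                                noise_sd = 0.2, seed = 1L) {
  if (length(cluster_shapes) < 2L) stop("need >= 2 cluster shapes")
  if (length(days) < 3L) stop("need >= 3 timepoints")
  k <- length(cluster_shapes)
  labels <- rep_len(seq_len(k), n_proteins)
  t_norm <- (days - min(days)) / (max(days) - min(days))
  templates <- vapply(cluster_shapes, function(f) f(t_norm),
                      numeric(length(days)))
  profiles <- with_substream(seed, "timecourse", {
    m <- t(templates[, labels, drop = FALSE]) +
      matrix(stats::rnorm(n_proteins * length(days), sd = noise_sd),
             nrow = n_proteins)
    m
  })
  dimnames(profiles) <- list(sprintf("T%05d", seq_len(n_proteins)),
                             paste0("day", days))
  names(labels) <- rownames(profiles)
  attr(labels, "shape_names") <- names(cluster_shapes)
  list(profiles = profiles, labels = labels, days = days)
}
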