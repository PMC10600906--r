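# Synthetic benchmark generator.
#
# Emulates the structure of the experimental 6mA benchmarks: equal numbers
# of positive and negative fixed-length windows (41 nt by default), adenine
# at the center position in both classes, negatives drawn i.i.d. from a
# background composition, positives drawn from a position weight matrix
# (PWM) that, within a halfwidth of the center, mixes a fixed consensus
# preference with the background at a tunable weight ("signal"). signal = 0
# makes positives statistically identical to negatives; signal = 1 makes the
# motif positions deterministic.

# Default consensus bases by offset from center: GGA upstream, CTT
# downstream (a DRACH-like arrangement); recycled for larger halfwidths.
fixture_consensus <- function(halfwidth) {
  up <- rep_len(rev(c("A", "G", "G", "C", "T")), halfwidth)
  down <- rep_len(c("C", "T", "T", "A", "G"), halfwidth)
  c(rev(up), down)  # offsets -halfwidth..-1 then 1..halfwidth
}

#' Configure a synthetic benchmark
#'
#' Defaults mirror the benchmark structure this generator stands in for:
#' balanced classes, 41-nt windows with a centered adenine, uniform
#' background, and a motif confined to +/- 3 positions around the center.
#'
#' @param n_pos number of positive sequences (default 400).
#' @param n_neg number of negative sequences (default 400).
#' @param length window length in nt, odd (default 41).
#' @param alphabet "DNA" or "RNA" (default "DNA").
#' @param signal motif strength in \[0, 1\]: mixing weight of the consensus
#'   preference against background at motif positions (default 0.8).
#' @param motif_halfwidth motif extent in positions either side of the
#'   center (default 3).
#' @param background length-4 base composition (A, C, G, T/U), summing to 1;
#'   default uniform.
#' @param species species tag stamped on the records (default "synthetic").
#' @param seed integer RNG seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_pos = 400L, n_neg = 400L, length = 41L,
                           alphabet = c("DNA", "RNA"), signal = 0.8,
                           motif_halfwidth = 3L,
                           background = rep(0.25, 4),
                           species = "synthetic", seed = 1L) {
  alphabet <- match.arg(alphabet)
  if (length %% 2L == 0L)
    stop("config error: length must be odd (center-A benchmark)",
         call. = FALSE)
  if (signal < 0 || signal > 1)
    stop("config error: signal must lie in [0, 1]", call. = FALSE)
  if (base::length(background) != 4L || abs(sum(background) - 1) > 1e-8 ||
      any(background < 0))
    stop("config error: background must be 4 probabilities summing to 1",
         call. = FALSE)
  if (motif_halfwidth < 1L || motif_halfwidth > (length - 1L) %/% 2L)
    stop("config error: motif_halfwidth out of range", call. = FALSE)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), alphabet = alphabet,
                 signal = signal,
                 motif_halfwidth = as.integer(motif_halfwidth),
                 background = as.numeric(background),
                 species = species, seed = as.integer(seed)),
            class = "fixture_config")
}

# Build the positive-class PWM (4 x L matrix of base probabilities).
# consensus: character vector of 2*halfwidth bases (offsets -hw..-1, 1..hw),
# or a 4 x 2*halfwidth probability matrix for interpolated motifs.
fixture_pwm <- function(config, consensus = NULL) {
  L <- config$length
  center <- (L + 1L) %/% 2L
  pwm <- matrix(config$background, nrow = 4L, ncol = L,
                dimnames = list(DNA_BASES, NULL))
  if (is.null(consensus)) consensus <- fixture_consensus(config$motif_halfwidth)
  offs <- setdiff(seq(-config$motif_halfwidth, config$motif_halfwidth), 0L)
  target <- if (is.matrix(consensus)) consensus else {
    m <- matrix(0, nrow = 4L, ncol = base::length(offs))
    m[cbind(match(consensus, DNA_BASES), seq_along(offs))] <- 1
    m
  }
  for (j in seq_along(offs)) {
    pwm[, center + offs[j]] <- config$signal * target[, j] +
      (1 - config$signal) * config$background
  }
  pwm[, center] <- c(1, 0, 0, 0)  # center adenine, both classes
  pwm
}

sample_from_pwm <- function(pwm, n) {
  L <- ncol(pwm)
  mat <- vapply(seq_len(L), function(pos)
    sample(DNA_BASES, n, replace = TRUE, prob = pwm[, pos]),
    character(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  apply(mat, 1L, paste0, collapse = "")
}

#' Generate a balanced synthetic benchmark
#'
#' Positives are drawn from the config's motif PWM, negatives i.i.d. from
#' the background; every sequence carries adenine at the center. With
#' `signal = 0` the two classes are drawn from the same distribution.
#' Deterministic for a fixed config (including its seed).
#'
#' @param config a `fixture_config`.
#' @param consensus optional override of the motif target (character vector
#'   or 4 x 2*halfwidth probability matrix); used by species-pair generation.
#' @return A `seq_records` data frame of n_pos + n_neg records.
#' @export
generate_benchmark <- function(config, consensus = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  pos_pwm <- fixture_pwm(config, consensus)
  neg_cfg <- config
  neg_cfg$signal <- 0
  neg_pwm <- fixture_pwm(neg_cfg)
  seqs <- with_local_seed(config$seed, {
    c(if (config$n_pos) sample_from_pwm(pos_pwm, config$n_pos),
      if (config$n_neg) sample_from_pwm(neg_pwm, config$n_neg))
  })
  recs <- seq_records(
    id = c(sprintf("pos_%d", seq_len(config$n_pos)),
           sprintf("neg_%d", seq_len(config$n_neg))),
    sequence = seqs,
    label = rep(c(1L, 0L), c(config$n_pos, config$n_neg)),
    species = config$species, alphabet = "DNA")
  if (config$alphabet == "RNA") recs <- normalize_alphabet(recs, "RNA")
  recs
}

#' Generate a pair of species-like benchmarks with tunable divergence
#'
#' Both datasets use randomly drawn motif consensus preferences (seeded from
#' `config_a$seed`). Dataset B's motif target is the interpolation
#' `(1 - divergence) * target_A + divergence * target_B_independent`:
#' divergence 0 gives both species one PWM (sampling seeds still differ),
#' divergence 1 gives independently sampled PWMs. Supports transfer-accuracy
#' monotonicity experiments at desk scale.
#'
#' @param config_a,config_b `fixture_config`s of equal length.
#' @param divergence motif divergence in \[0, 1\].
#' @return list with `seq_records` elements `a` and `b`.
#' @export
generate_species_pair <- function(config_a, config_b, divergence = 0) {
  stopifnot(inherits(config_a, "fixture_config"),
            inherits(config_b, "fixture_config"))
  if (config_a$length != config_b$length)
    stop("config error: species pair requires equal lengths", call. = FALSE)
  if (config_a$motif_halfwidth != config_b$motif_halfwidth)
    stop("config error: species pair requires equal motif halfwidths",
         call. = FALSE)
  if (divergence < 0 || divergence > 1)
    stop("config error: divergence must lie in [0, 1]", call. = FALSE)
  n_motif <- 2L * config_a$motif_halfwidth
  cons <- with_local_seed(config_a$seed, list(
    a = sample(DNA_BASES, n_motif, replace = TRUE),
    b = sample(DNA_BASES, n_motif, replace = TRUE)))
  onehot <- function(bases) {
    m <- matrix(0, nrow = 4L, ncol = base::length(bases))
    m[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 1
    m
  }
  target_a <- onehot(cons$a)
  target_b <- (1 - divergence) * target_a + divergence * onehot(cons$b)
  # distinct sampling sub-seeds so divergence = 0 still yields different draws
  cfg_a <- config_a; cfg_a$seed <- config_a$seed * 2L + 1L
  cfg_b <- config_b; cfg_b$seed <- config_b$seed * 2L + 2L
  list(a = generate_benchmark(cfg_a, consensus = target_a),
       b = generate_benchmark(cfg_b, consensus = target_b))
}

#' Write a fixture dataset as a FASTA pair plus a JSON config sidecar
#'
#' @param records a `seq_records` data frame (both classes).
#' @param config the `fixture_config` that produced it.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "fixture").
#' @return named character vector of the three written paths, invisibly.
#' @export
write_fixture <- function(records, config, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos_path <- file.path(dir, paste0(prefix, "_pos.fasta"))
  neg_path <- file.path(dir, paste0(prefix, "_neg.fasta"))
  cfg_path <- file.path(dir, paste0(prefix, "_config.json"))
  write_fasta(records[records$label == 1L, , drop = FALSE], pos_path)
  write_fasta(records[records$label == 0L, , drop = FALSE], neg_path)
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             cfg_path)
  invisible(c(positive = pos_path, negative = neg_path, config = cfg_path))
}
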