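#' Configuration for the synthetic benchmark generator
#'
#' Describes two classes of cytosine-centred windows: negatives are drawn
#' i.i.d. from the background composition; positives additionally carry a
#' planted position-weight-matrix (PWM) motif next to the central cytosine.
#' The PWM gives the consensus base probability `0.25 + 0.75 * effect` at
#' each motif position (other bases share the remainder uniformly), so
#' `effect = 0` makes the classes identical and `effect = 1` plants a
#' deterministic consensus word.
#'
#' @param n_pos,n_neg class sizes.
#' @param L window length (odd, default 41); the centre base is forced to C
#'   in both classes.
#' @param effect motif strength in \[0, 1\].
#' @param motif_width number of motif positions (default 8).
#' @param motif_offset start of the motif relative to the centre (default 2,
#'   i.e. the motif occupies positions centre+2 .. centre+motif_width+1).
#' @param background_composition probabilities of A, C, G, T (sum to 1).
#' @param modqv_rate fraction of samples given a synthetic modQV value.
#' @param seed integer RNG seed.
#' @return a list of class `mc4_generator_config`.
#' @export
generator_config <- function(n_pos = 300L, n_neg = 300L, L = 41L, effect = 0.6,
                             motif_width = 8L, motif_offset = 2L,
                             background_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             modqv_rate = 0.5, seed = 1L) {
  stopifnot(L %% 2L == 1L, effect >= 0, effect <= 1, motif_width >= 1L)
  if (abs(sum(background_composition) - 1) > 1e-9) {
    stop("background_composition must sum to 1", call. = FALSE)
  }
  centre <- (L + 1L) %/% 2L
  lo <- centre + motif_offset
  hi <- lo + motif_width - 1L
  if (lo < 1L || hi > L) {
    stop("motif window [", lo, ", ", hi, "] overflows the ", L, "-bp sequence",
         call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 L = as.integer(L), effect = effect,
                 motif_width = as.integer(motif_width),
                 motif_offset = as.integer(motif_offset),
                 background_composition = background_composition,
                 modqv_rate = modqv_rate, seed = as.integer(seed)),
            class = "mc4_generator_config")
}

#' Positive-class PWM implied by a generator configuration
#'
#' @param config an [generator_config()] object.
#' @return a 4 x motif_width matrix of base probabilities (rows A, C, G, T).
#' @export
generator_pwm <- function(config) {
  bases <- c("A", "C", "G", "T")
  # fixed composition-biased consensus word, as real methylation motifs are
  consensus <- rep(c("G", "A", "C", "A", "G", "G", "T", "A"),
                   length.out = config$motif_width)
  p_hit <- 0.25 + 0.75 * config$effect
  pwm <- matrix((1 - p_hit) / 3, nrow = 4, ncol = config$motif_width,
                dimnames = list(bases, NULL))
  for (j in seq_len(config$motif_width)) pwm[consensus[j], j] <- p_hit
  pwm
}

#' Kullback-Leibler divergence of the planted motif from background
#'
#' Summed over motif positions; closed-form monotone function of `effect`,
#' useful for checking that the effect knob really orders signal strength.
#'
#' @param config an [generator_config()] object.
#' @return non-negative scalar (nats).
#' @export
motif_kl <- function(config) {
  pwm <- generator_pwm(config)
  bg <- config$background_composition
  sum(apply(pwm, 2, function(p) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / bg[nz]))
  }))
}

#' Generate labelled synthetic 4mC windows
#'
#' Draws `n_pos` motif-bearing positives and `n_neg` background negatives per
#' the configuration, all with a central C; byte-identical output for a fixed
#' config (including seed).
#'
#' @param config an [generator_config()] object.
#' @return an `mc4_samples` table with synthetic modQV values attached to a
#'   `modqv_rate` fraction of samples.
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "mc4_generator_config"))
  rng <- local_rng(config$seed)
  bases <- c("A", "C", "G", "T")
  L <- config$L
  centre <- (L + 1L) %/% 2L
  n <- config$n_pos + config$n_neg
  draw_background <- function(m) {
    matrix(bases[rng$sample_int(4L, m * L, replace = TRUE,
                                prob = config$background_composition)],
           nrow = m, ncol = L)
  }
  seqs <- draw_background(n)
  labels <- rep(c("pos", "neg"), c(config$n_pos, config$n_neg))
  if (config$n_pos > 0L && config$motif_width > 0L) {
    pwm <- generator_pwm(config)
    lo <- centre + config$motif_offset
    for (j in seq_len(config$motif_width)) {
      seqs[seq_len(config$n_pos), lo + j - 1L] <-
        bases[rng$sample_int(4L, config$n_pos, replace = TRUE, prob = pwm[, j])]
    }
  }
  seqs[, centre] <- "C"
  seq_str <- apply(seqs, 1, paste0, collapse = "")
  modqv <- rep(NA_real_, n)
  has_q <- rng$runif(n) < config$modqv_rate
  # synthetic modQV: kinetic-deviation-like scores, non-negative
  modqv[has_q] <- round(abs(20 + 15 * stats::qnorm(rng$runif(sum(has_q)))), 1)
  samples <- new_samples(sprintf("syn%05d", seq_len(n)), seq_str, labels, modqv)
  validate_samples(samples, L = L)
  samples
}
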