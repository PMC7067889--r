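#' @include sequence_io.R
NULL

#' The eight preliminary encoding schemes, in canonical order
#'
#' BKF (binary + k-mer frequency), DBPF (dinucleotide binary profile and
#' frequency), KNN (nearest-neighbour label features), PCP (physicochemical
#' dinucleotide properties), MMI (multivariate mutual information of
#' composition), PseDNC (pseudo dinucleotide composition), PseEIIP
#' (EIIP-weighted trinucleotide frequencies) and RFHCP
#' (ring/hydrogen/chemical-group codes with cumulative frequency).
#'
#' @export
mc4_schemes <- c("BKF", "DBPF", "KNN", "PCP", "MMI", "PseDNC", "PseEIIP", "RFHCP")

BASES <- c("A", "C", "G", "T")

# Electron-ion interaction pseudopotentials of the four nucleotides.
EIIP <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

# B-DNA dinucleotide step parameters (twist/tilt/roll in degrees, shift/
# slide/rise in Angstrom), crystallographic ensemble averages adapted from
# Olson et al. (1998) PNAS 95:11163. The ten unique steps are listed; the
# six complementary steps are derived below (twist/roll/slide/rise equal,
# tilt/shift negated).
PCP_RAW_UNIQUE <- matrix(c(
  # twist  tilt  roll  shift slide  rise
    35.1, -1.4,  0.7, -0.03, -0.08, 3.27,  # AA
    31.5, -0.1,  0.7,  0.13, -0.58, 3.36,  # AC
    31.9, -1.7,  4.5,  0.09, -0.25, 3.34,  # AG
    29.3,  0.0,  1.1,  0.00, -0.59, 3.31,  # AT
    37.3,  0.5,  4.7,  0.09,  0.53, 3.33,  # CA
    32.9, -0.1,  3.6,  0.05, -0.22, 3.42,  # CC
    36.1,  0.0,  5.4,  0.00,  0.41, 3.39,  # CG
    36.3, -1.5,  1.9, -0.28,  0.09, 3.37,  # GA
    33.6,  0.0,  0.3,  0.00, -0.38, 3.40,  # GC
    37.8,  0.0,  3.3,  0.00,  0.05, 3.42   # TA
), nrow = 10, byrow = TRUE,
  dimnames = list(c("AA","AC","AG","AT","CA","CC","CG","GA","GC","TA"),
                  c("twist","tilt","roll","shift","slide","rise")))

pcp_table <- local({
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  all16 <- as.vector(outer(BASES, BASES, paste0))
  tab <- matrix(NA_real_, 16, 6, dimnames = list(all16, colnames(PCP_RAW_UNIQUE)))
  for (d in all16) {
    if (d %in% rownames(PCP_RAW_UNIQUE)) {
      tab[d, ] <- PCP_RAW_UNIQUE[d, ]
    } else {
      rc <- paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
      v <- PCP_RAW_UNIQUE[rc, ]
      v[c("tilt", "shift")] <- -v[c("tilt", "shift")]
      tab[d, ] <- v
    }
  }
  # standardized to zero mean / unit sd over the 16 dinucleotides, as is
  # conventional for pseudo-composition correlation functions
  scale(tab)[, ]
})

default_encoder_params <- function() {
  list(bkf_k = 2:4,
       psednc_lambda = 3L, psednc_w = 0.1,
       knn_fractions = seq(0.02, 0.20, by = 0.02))
}

merge_params <- function(params) {
  p <- default_encoder_params()
  if (!is.null(params)) p[names(params)] <- params
  p
}

#' Feature-vector length of an encoding scheme
#'
#' Closed-form length for each scheme at window length `L`. With the default
#' parameters and `L = 41`: BKF 500 (one-hot 4x41 plus k-mer frequencies for
#' k = 2,3,4), DBPF 680, KNN 10, PCP 240, MMI 30, PseDNC 19, PseEIIP 64,
#' RFHCP 164.
#'
#' @param scheme one of [mc4_schemes].
#' @param L window length.
#' @param params optional list overriding encoder parameters
#'   (`bkf_k`, `psednc_lambda`, `psednc_w`, `knn_fractions`).
#' @return integer length.
#' @export
feature_length <- function(scheme, L = 41L, params = NULL) {
  p <- merge_params(params)
  switch(match_scheme(scheme),
         BKF = 4L * L + sum(4L^p$bkf_k),
         DBPF = (L - 1L) * 17L,
         KNN = length(p$knn_fractions),
         PCP = (L - 1L) * 6L,
         MMI = 10L + 20L,
         PseDNC = 16L + p$psednc_lambda,
         PseEIIP = 64L,
         RFHCP = 4L * L)
}

match_scheme <- function(scheme) {
  i <- match(toupper(scheme), toupper(mc4_schemes))
  if (is.na(i)) stop("unknown encoding scheme: ", scheme, call. = FALSE)
  mc4_schemes[i]
}

seq_to_int <- function(sequence) {
  s <- match(strsplit(sequence, "")[[1]], BASES)
  if (anyNA(s)) stop("sequence contains non-ACGT residue", call. = FALSE)
  s
}

# Integer codes (0-based) of all overlapping k-mers of s (1..4 ints).
kmer_codes <- function(s, k) {
  L <- length(s)
  if (L < k) stop("sequence shorter than k = ", k, call. = FALSE)
  v <- s - 1L
  codes <- v[seq_len(L - k + 1L)]
  if (k > 1L) for (j in 2:k) codes <- codes * 4L + v[j:(L - k + j)]
  codes
}

kmer_freq <- function(s, k) {
  codes <- kmer_codes(s, k)
  tabulate(codes + 1L, nbins = 4L^k) / length(codes)
}

kmer_names <- function(k) {
  g <- expand.grid(rep(list(BASES), k))[, k:1, drop = FALSE]
  apply(g, 1, paste0, collapse = "")
}

encode_bkf <- function(s, p) {
  onehot <- as.vector(vapply(s, function(b) as.numeric(seq_len(4) == b),
                             numeric(4)))
  c(onehot, unlist(lapply(p$bkf_k, function(k) kmer_freq(s, k))))
}

encode_dbpf <- function(s, p) {
  L <- length(s)
  codes <- kmer_codes(s, 2L)          # 0..15 per dinucleotide position
  out <- numeric((L - 1L) * 17L)
  counts <- integer(16)
  for (j in seq_len(L - 1L)) {
    counts[codes[j] + 1L] <- counts[codes[j] + 1L] + 1L
    block <- numeric(17)
    block[codes[j] + 1L] <- 1
    block[17L] <- counts[codes[j] + 1L] / j   # running frequency up to j
    out[((j - 1L) * 17L + 1L):(j * 17L)] <- block
  }
  out
}

encode_pcp <- function(s, p) {
  codes <- kmer_codes(s, 2L) + 1L
  # codes are base-4 with the first base as the high digit
  code_names <- kmer_names(2L)
  as.vector(t(pcp_table[code_names[codes], , drop = FALSE]))
}

unordered_kmers <- function(k) {
  combs <- utils::combn(rep(1:4, k), k, simplify = FALSE)
  sorted <- unique(lapply(combs, sort))
  sorted[order(vapply(sorted, function(x) sum(x * 4^((k - 1):0)), 0))]
}

encode_mmi <- function(s, p) {
  L <- length(s)
  f1 <- tabulate(s, 4L) / L
  # unordered adjacent pair frequencies
  pair_counts <- matrix(0, 4, 4)
  for (j in seq_len(L - 1L)) {
    a <- sort(c(s[j], s[j + 1L]))
    pair_counts[a[1], a[2]] <- pair_counts[a[1], a[2]] + 1
  }
  fpair <- pair_counts / (L - 1L)
  pairs <- unordered_kmers(2L)
  i2 <- vapply(pairs, function(xy) {
    fxy <- fpair[xy[1], xy[2]]
    if (fxy == 0 || f1[xy[1]] == 0 || f1[xy[2]] == 0) return(0)
    fxy * log(fxy / (f1[xy[1]] * f1[xy[2]]))
  }, 0)
  # unordered adjacent triple frequencies
  trip_counts <- array(0, c(4, 4, 4))
  for (j in seq_len(L - 2L)) {
    a <- sort(s[j:(j + 2L)])
    trip_counts[a[1], a[2], a[3]] <- trip_counts[a[1], a[2], a[3]] + 1
  }
  ftrip <- trip_counts / (L - 2L)
  triples <- unordered_kmers(3L)
  i3 <- vapply(triples, function(xyz) {
    x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
    fs <- c(f1[x], f1[y], f1[z],
            fpair[x, y], fpair[x, z], fpair[y, z],
            ftrip[x, y, z])
    if (any(fs == 0)) return(0)
    # pointwise interaction information weighted by the triple frequency
    fs[7] * log(fs[4] * fs[5] * fs[6] / (fs[1] * fs[2] * fs[3] * fs[7]))
  }, 0)
  c(i2, i3)
}

psednc_theta <- function(s, lambda) {
  codes <- kmer_codes(s, 2L) + 1L
  code_names <- kmer_names(2L)
  P <- pcp_table[code_names[codes], , drop = FALSE]   # (L-1) x 6
  n <- nrow(P)
  vapply(seq_len(lambda), function(j) {
    if (n - j < 1L) return(0)
    d <- P[seq_len(n - j), , drop = FALSE] - P[(1L + j):n, , drop = FALSE]
    mean(rowMeans(d^2))
  }, 0)
}

encode_psednc <- function(s, p) {
  lambda <- p$psednc_lambda; w <- p$psednc_w
  if (length(s) - 1L <= lambda) stop("sequence too short for lambda = ", lambda,
                                     call. = FALSE)
  f <- kmer_freq(s, 2L)
  theta <- psednc_theta(s, lambda)
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

encode_pseeiip <- function(s, p) {
  f <- kmer_freq(s, 3L)
  tri <- kmer_names(3L)
  eiip_sum <- vapply(tri, function(t3) sum(EIIP[strsplit(t3, "")[[1]]]), 0)
  unname(eiip_sum * f)
}

# ring (purine), hydrogen-bond strength (strong), functional/amino group
RFHCP_BITS <- matrix(c(1, 0, 1,   # A
                       0, 1, 1,   # C
                       1, 1, 0,   # G
                       0, 0, 0),  # T
                     nrow = 4, byrow = TRUE,
                     dimnames = list(BASES, c("ring", "hbond", "amino")))

encode_rfhcp <- function(s, p) {
  L <- length(s)
  cum <- numeric(L)
  counts <- integer(4)
  for (i in seq_len(L)) {
    counts[s[i]] <- counts[s[i]] + 1L
    cum[i] <- counts[s[i]] / i
  }
  as.vector(rbind(t(RFHCP_BITS[s, , drop = FALSE]), cum))
}

#' Encode one DNA window under a preliminary feature scheme
#'
#' Pure function of the sequence (and parameters). The KNN scheme needs a
#' labelled reference set and is therefore handled by [encode_knn()];
#' requesting it here is an error.
#'
#' @param sample a sequence string, or a single-row `mc4_samples` table.
#' @param scheme one of [mc4_schemes] except `"KNN"`.
#' @param params optional encoder parameter overrides, see [feature_length()].
#' @return numeric feature vector of length `feature_length(scheme, L)`.
#' @examples
#' length(encode(strrep("AC", 20) |> paste0("C"), "PseEIIP"))
#' @export
encode <- function(sample, scheme, params = NULL) {
  scheme <- match_scheme(scheme)
  if (scheme == "KNN") {
    stop("KNN encoding needs a reference set; use encode_knn()", call. = FALSE)
  }
  sequence <- if (inherits(sample, "mc4_samples")) sample$sequence[1] else sample
  s <- seq_to_int(sequence)
  p <- merge_params(params)
  fn <- switch(scheme, BKF = encode_bkf, DBPF = encode_dbpf, PCP = encode_pcp,
               MMI = encode_mmi, PseDNC = encode_psednc,
               PseEIIP = encode_pseeiip, RFHCP = encode_rfhcp)
  v <- fn(s, p)
  stopifnot(length(v) == feature_length(scheme, length(s), p), all(is.finite(v)))
  unname(v)
}

#' Nearest-neighbour label features for one window
#'
#' Similarity between two equal-length windows is the fraction of matching
#' positions. For each fraction `f` in `k_fractions` the feature value is the
#' proportion of positive labels among the `ceiling(f * n_refs)` most similar
#' references; ties in similarity are broken by reference input order.
#'
#' @param sequence query sequence string.
#' @param reference_set an `mc4_samples` table excluding the query itself.
#' @param k_fractions neighbourhood sizes as fractions of the reference set.
#' @return numeric vector, one value per fraction.
#' @export
encode_knn <- function(sequence, reference_set,
                       k_fractions = seq(0.02, 0.20, by = 0.02)) {
  if (!inherits(reference_set, "mc4_samples") || nrow(reference_set) == 0L) {
    stop("reference set must be a non-empty mc4_samples table", call. = FALSE)
  }
  q <- seq_to_int(sequence)
  sims <- vapply(reference_set$sequence,
                 function(r) mean(seq_to_int(r) == q), 0, USE.NAMES = FALSE)
  ord <- order(-sims, seq_along(sims))
  pos <- reference_set$label[ord] == "pos"
  n <- length(pos)
  vapply(k_fractions, function(f) mean(pos[seq_len(min(n, max(1L, ceiling(f * n))))]), 0)
}

onehot_matrix <- function(samples) {
  n <- nrow(samples)
  L <- nchar(samples$sequence[1])
  M <- matrix(0, n, 4L * L)
  for (i in seq_len(n)) {
    s <- seq_to_int(samples$sequence[i])
    M[i, (seq_len(L) - 1L) * 4L + s] <- 1
  }
  M
}

#' Encode a whole dataset under one scheme
#'
#' Rows follow the sample order. For the KNN scheme a fold assignment is
#' mandatory and every row is computed *out-of-fold*: sample i's references
#' are all samples in other folds, so no row ever sees its own fold's labels
#' (leakage guard).
#'
#' @param samples an `mc4_samples` table.
#' @param scheme one of [mc4_schemes].
#' @param fold_assignment an [stratified_folds()] vector (required for KNN).
#' @param params optional encoder parameter overrides.
#' @return an `mc4_encoded` matrix (n x feature_length) with attributes
#'   `scheme`, `params` and rownames = sample ids.
#' @export
encode_dataset <- function(samples, scheme, fold_assignment = NULL, params = NULL) {
  scheme <- match_scheme(scheme)
  p <- merge_params(params)
  n <- nrow(samples)
  L <- if (n) nchar(samples$sequence[1]) else 41L
  d <- feature_length(scheme, L, p)
  if (n == 0L) {
    M <- matrix(numeric(0), 0L, d)
  } else if (scheme == "KNN") {
    if (is.null(fold_assignment)) {
      stop("KNN dataset encoding requires a fold assignment (out-of-fold references)",
           call. = FALSE)
    }
    stopifnot(length(fold_assignment) == n)
    # identity similarity in one GEMM: one-hot dot product = #matching positions
    B <- onehot_matrix(samples)
    S <- tcrossprod(B)
    is_pos <- samples$label == "pos"
    M <- matrix(0, n, d)
    for (i in seq_len(n)) {
      refs <- which(fold_assignment != fold_assignment[i])
      sims <- S[i, refs]
      ord <- refs[order(-sims, seq_along(refs))]
      pos <- is_pos[ord]
      m <- length(pos)
      M[i, ] <- vapply(p$knn_fractions,
                       function(f) mean(pos[seq_len(min(m, max(1L, ceiling(f * m))))]), 0)
    }
  } else {
    M <- t(vapply(samples$sequence,
                  function(sq) encode(sq, scheme, p), numeric(d),
                  USE.NAMES = FALSE))
  }
  rownames(M) <- samples$id
  structure(M, scheme = scheme, params = p[encoder_param_keys(scheme)],
            class = c("mc4_encoded", class(M)))
}

encoder_param_keys <- function(scheme) {
  switch(scheme, BKF = "bkf_k", PseDNC = c("psednc_lambda", "psednc_w"),
         KNN = "knn_fractions", character(0))
}

#' Export an encoded matrix as TSV with a JSON sidecar
#'
#' @param m an `mc4_encoded` (or plain) matrix with rownames.
#' @param path TSV output path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scheme = attr(m, "scheme"), params = attr(m, "params"),
               n = nrow(m), length = ncol(m))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an encoded matrix written by [write_encoded()]
#' @param path TSV path.
#' @return an `mc4_encoded` matrix.
#' @export
read_encoded <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(m, "scheme") <- meta$scheme
    attr(m, "params") <- meta$params
  }
  structure(m, class = c("mc4_encoded", class(m)))
}
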