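#' @include metrics.R
NULL

# A sample table is a data.frame with columns id, sequence, label ("pos"/"neg")
# and modqv (numeric, NA when absent), classed "mc4_samples".

new_samples <- function(id, sequence, label, modqv = NA_real_) {
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   label = as.character(label),
                   modqv = as.numeric(modqv),
                   stringsAsFactors = FALSE)
  class(df) <- c("mc4_samples", "data.frame")
  df
}

#' @export
print.mc4_samples <- function(x, ...) {
  cat("<mc4_samples> ", nrow(x), " windows of ",
      if (nrow(x)) nchar(x$sequence[1]) else NA, " bp (",
      sum(x$label == "pos"), " pos / ", sum(x$label == "neg"), " neg)\n",
      sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Validate a table of fixed-length DNA windows
#'
#' Checks sequence length, alphabet and (optionally) the centre-cytosine
#' convention: every window is expected to carry the putative 4mC cytosine at
#' the central, 1-based position `(L + 1) / 2` — negatives too, since they are
#' centred on cytosines that were *not* called modified.
#'
#' @param samples an `mc4_samples` table.
#' @param L expected window length (odd; default 41).
#' @param centre_check `"fail"` (default), `"warn"` or `"none"` for windows
#'   whose central base is not C.
#' @return `samples`, invisibly, after validation.
#' @export
validate_samples <- function(samples, L = 41L, centre_check = c("fail", "warn", "none")) {
  centre_check <- match.arg(centre_check)
  stopifnot(inherits(samples, "mc4_samples"))
  if (nrow(samples) == 0L) return(invisible(samples))
  len <- nchar(samples$sequence)
  bad <- which(len != L)
  if (length(bad)) {
    stop("record '", samples$id[bad[1]], "' has length ", len[bad[1]],
         ", expected ", L, call. = FALSE)
  }
  for (i in seq_len(nrow(samples))) {
    res <- gregexpr("[^ACGT]", samples$sequence[i])[[1]]
    if (res[1] != -1L) {
      stop("record '", samples$id[i], "' contains non-ACGT residue at position ",
           res[1], call. = FALSE)
    }
  }
  if (centre_check != "none") {
    centre <- (L + 1L) %/% 2L
    cb <- substr(samples$sequence, centre, centre)
    off <- which(cb != "C")
    if (length(off)) {
      msg <- paste0("record '", samples$id[off[1]], "' has '", cb[off[1]],
                    "' at the centre position ", centre, ", expected 'C'")
      if (centre_check == "fail") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  if (!all(samples$label %in% c("pos", "neg"))) {
    stop("labels must be 'pos'/'neg'", call. = FALSE)
  }
  invisible(samples)
}

#' Read labelled DNA windows from FASTA
#'
#' Sequences are uppercased and U is converted to T; any other non-ACGT
#' residue is an error. Labels come either from a header tag (`|pos` /
#' `|neg`, also accepting `|1` / `|0`) or from a sidecar TSV
#' (`id<TAB>label`). An optional metadata TSV (`id<TAB>modqv`) attaches the
#' SMRT modification quality value used by [filter_by_modqv()].
#'
#' @param fasta_path path to a FASTA file of fixed-length windows.
#' @param labels_source `"header"` (default) or the path of a labels TSV.
#' @param metadata_path optional path of a modQV metadata TSV.
#' @param L expected window length.
#' @param centre_check passed to [validate_samples()].
#' @return an `mc4_samples` table in file order.
#' @export
read_samples <- function(fasta_path, labels_source = "header",
                         metadata_path = NULL, L = 41L,
                         centre_check = "fail") {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path, call. = FALSE)
  set <- Biostrings::readBStringSet(fasta_path)
  ids <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (identical(labels_source, "header")) {
    m <- regmatches(ids, regexec("^(.*)\\|(pos|neg|1|0)\\s*$", ids))
    ok <- lengths(m) == 3L
    if (!all(ok)) {
      stop("record '", ids[!ok][1], "' has no |pos / |neg header tag", call. = FALSE)
    }
    base_ids <- vapply(m, `[`, "", 2L)
    labels <- vapply(m, `[`, "", 3L)
    labels <- ifelse(labels %in% c("pos", "1"), "pos", "neg")
    ids <- base_ids
  } else {
    tab <- utils::read.table(labels_source, sep = "\t", header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = "character")
    ids <- sub("\\s.*$", "", ids)  # FASTA description after first whitespace
    idx <- match(ids, tab$id)
    if (anyNA(idx)) {
      stop("record '", ids[is.na(idx)][1], "' has no label in ", labels_source,
           call. = FALSE)
    }
    lab <- tolower(tab$label[idx])
    if (!all(lab %in% c("1", "0", "pos", "neg"))) {
      stop("labels TSV values must be one of 1/0/pos/neg", call. = FALSE)
    }
    labels <- ifelse(lab %in% c("1", "pos"), "pos", "neg")
  }
  modqv <- rep(NA_real_, length(ids))
  if (!is.null(metadata_path)) {
    meta <- utils::read.table(metadata_path, sep = "\t", header = FALSE,
                              col.names = c("id", "modqv"),
                              colClasses = c("character", "numeric"))
    modqv <- meta$modqv[match(ids, meta$id)]
  }
  samples <- new_samples(ids, seqs, labels, modqv)
  validate_samples(samples, L = L, centre_check = centre_check)
  samples
}

#' Write windows as FASTA (+ labels and metadata TSVs)
#'
#' Inverse of [read_samples()]: emits `windows.fasta` with `id|pos` /
#' `id|neg` headers, a `labels.tsv` sidecar and, when any modQV is present,
#' `metadata.tsv`.
#'
#' @param samples an `mc4_samples` table.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_benchmark <- function(samples, out_dir) {
  stopifnot(inherits(samples, "mc4_samples"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create directory ", out_dir, call. = FALSE)
  }
  fasta <- file.path(out_dir, "windows.fasta")
  labels <- file.path(out_dir, "labels.tsv")
  lines <- character(0)
  if (nrow(samples)) {
    lines <- as.vector(rbind(paste0(">", samples$id, "|", samples$label),
                             samples$sequence))
  }
  writeLines(lines, fasta)
  utils::write.table(
    data.frame(id = samples$id, label = ifelse(samples$label == "pos", 1L, 0L)),
    labels, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(fasta = fasta, labels = labels)
  if (any(!is.na(samples$modqv))) {
    meta <- file.path(out_dir, "metadata.tsv")
    keep <- !is.na(samples$modqv)
    utils::write.table(data.frame(id = samples$id[keep], modqv = samples$modqv[keep]),
                       meta, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, metadata = meta)
  }
  paths
}

#' Filter windows by SMRT modification quality value (modQV)
#'
#' The SMRT Methylome Analysis convention uses modQV = 30 as the default
#' threshold for calling a position modified; the source protocol removes
#' samples with modQV above 30, and that literal rule is the default here
#' (`drop_above`). `drop_below` gives the opposite reading. Samples without a
#' modQV pass unchanged in either mode.
#'
#' @param samples an `mc4_samples` table.
#' @param threshold non-negative modQV cutoff (default 30).
#' @param mode `"drop_above"` (default) removes samples with modqv >
#'   threshold; `"drop_below"` removes samples with modqv < threshold.
#' @return the filtered table, original order preserved.
#' @export
filter_by_modqv <- function(samples, threshold = 30,
                            mode = c("drop_above", "drop_below")) {
  mode <- match.arg(mode)
  stopifnot(inherits(samples, "mc4_samples"))
  if (threshold < 0) stop("modQV threshold must be non-negative", call. = FALSE)
  if (nrow(samples) == 0L) return(samples)
  q <- samples$modqv
  drop <- if (mode == "drop_above") !is.na(q) & q > threshold else !is.na(q) & q < threshold
  samples[!drop, , drop = FALSE]
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence string. This is a
#' deliberately weaker built-in stand-in for similarity-based redundancy
#' removal: when a CD-HIT binary is available, pass its path via `cdhit_path`
#' to cluster at `cdhit_threshold` identity instead.
#'
#' @param samples an `mc4_samples` table.
#' @param cdhit_path optional path to a `cd-hit-est` binary.
#' @param cdhit_threshold sequence-identity cutoff for CD-HIT (default 0.8).
#' @param verbose log the number of removed sequences.
#' @return the deduplicated table.
#' @export
dedup_exact <- function(samples, cdhit_path = NULL, cdhit_threshold = 0.8,
                        verbose = TRUE) {
  stopifnot(inherits(samples, "mc4_samples"))
  if (!is.null(cdhit_path)) {
    if (!nzchar(Sys.which(cdhit_path)) && !file.exists(cdhit_path)) {
      stop("cdhit binary not found: ", cdhit_path, call. = FALSE)
    }
    td <- tempfile("cdhit"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    paths <- write_benchmark(samples, td)
    out <- file.path(td, "clustered.fasta")
    status <- system2(cdhit_path, c("-i", paths[["fasta"]], "-o", out,
                                    "-c", cdhit_threshold, "-n", "5"),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("cd-hit-est exited with status ", status, call. = FALSE)
    kept <- read_samples(out, centre_check = "none",
                         L = nchar(samples$sequence[1]))
    res <- samples[samples$id %in% kept$id, , drop = FALSE]
  } else {
    res <- samples[!duplicated(samples$sequence), , drop = FALSE]
  }
  removed <- nrow(samples) - nrow(res)
  if (verbose && removed > 0L) {
    message("dedup: removed ", removed, " of ", nrow(samples), " sequences",
            if (is.null(cdhit_path)) " (exact duplicates only; weaker than similarity clustering)")
  }
  res
}

#' Stratified k-fold assignment
#'
#' Shuffles each class with a seeded RNG and deals samples round-robin to
#' folds, so fold sizes differ by at most one and the class ratio of every
#' fold stays close to the global ratio. Deterministic for a fixed seed.
#'
#' @param samples an `mc4_samples` table, or a vector of labels.
#' @param k number of folds (default 3).
#' @param seed integer RNG seed.
#' @return an integer vector of fold indices in `0..k-1`, one per sample,
#'   with attributes `k` and `seed` (class `mc4_folds`).
#' @export
stratified_folds <- function(samples, k = 3L, seed = 1L) {
  labels <- if (inherits(samples, "mc4_samples")) samples$label else as.character(samples)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class '", names(tab)[tab < k][1], "' has fewer than k = ", k,
         " members", call. = FALSE)
  }
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    fold[idx] <- (seq_along(idx) - 1L) %% k
  }
  structure(fold, k = as.integer(k), seed = as.integer(seed),
            class = "mc4_folds")
}

# Seeded RNG helper that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    st
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_perm = function(n) with_state(function() sample.int(n)),
    runif = function(n, ...) with_state(function() stats::runif(n, ...)),
    sample_int = function(n, size, replace = FALSE, prob = NULL)
      with_state(function() sample.int(n, size, replace = replace, prob = prob)),
    draw_seed = function() with_state(function() sample.int(.Machine$integer.max, 1L))
  )
}
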