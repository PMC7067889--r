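#' @include final_net.R
NULL

# FNV-1a hash of a string, reported in hex; used to fingerprint configs in
# the manifest without external digest dependencies.
fnv1a <- function(s) {
  h <- 0x811c9dc5
  for (b in utf8ToInt(s)) {
    # xor with a byte only touches the low 8 bits
    h <- (h - h %% 256) + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full 4mC prediction pipeline with cross-validated evaluation
#'
#' Executes every stage on one dataset under a single stratified fold
#' assignment: optional modQV filtering and exact deduplication, the eight
#' preliminary encodings, the per-encoding CNN+BLSTM extractors (out-of-fold
#' advanced features), the iterative stacking ensemble, and the final
#' classifier, which is itself evaluated out-of-fold over the same folds so
#' the reported metrics are leakage-free held-out estimates.
#'
#' @param samples an `mc4_samples` table (e.g. from [generate_samples()] or
#'   [read_samples()]).
#' @param k folds for every cross-validated stage (default 3).
#' @param net_config an [network_config()].
#' @param final_config an [final_net_config()].
#' @param learners an [learner_set()].
#' @param max_iter,tol stacking iteration controls (see [stack_iterate()]).
#' @param modqv_threshold apply [filter_by_modqv()] first when non-`NULL`.
#' @param dedup apply [dedup_exact()] first.
#' @param encoder_params optional encoder parameter overrides.
#' @param seed master seed; fans out to fold assignment, network training,
#'   stacking learners and the final net.
#' @param out_dir when non-`NULL`, artifacts (matrices, calls, report,
#'   manifest) are written there.
#' @param verbose print per-stage progress.
#' @return a list of class `mc4_run`: `report` (held-out [metric_report()]),
#'   `oof_probs`, `bundle`, `enriched`, `final` (refit model),
#'   `final_fold_models`, `folds`, `samples`, `manifest`.
#' @export
run_pipeline <- function(samples, k = 3L,
                         net_config = network_config(),
                         final_config = final_net_config(),
                         learners = learner_set(),
                         max_iter = 10L, tol = 1e-4,
                         modqv_threshold = NULL, dedup = FALSE,
                         encoder_params = NULL,
                         seed = 1L, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(samples, "mc4_samples"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    if (verbose) message(sprintf("[%s] done in %.1fs", name,
                                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }
  if (!is.null(modqv_threshold)) {
    samples <- stage("filter", filter_by_modqv(samples, modqv_threshold))
  }
  if (dedup) samples <- stage("dedup", dedup_exact(samples, verbose = verbose))
  y <- as_binary_label(samples$label)
  folds <- stratified_folds(samples, k = k, seed = seed)
  net_config$seed <- seed + 1L
  bundle <- stage("advanced",
                  train_advanced_features(samples, folds, net_config,
                                          params = encoder_params,
                                          verbose = verbose))
  enriched <- stage("stack",
                    stack_iterate(bundle$advanced, y, folds, learners,
                                  max_iter = max_iter, tol = tol,
                                  seed = seed + 2L, verbose = verbose))
  # held-out evaluation of the final net over the same folds
  fc <- final_config
  oof <- rep(NA_real_, length(y))
  final_fold_models <- list()
  final_train_ids <- list()
  stage("final", for (f in sort(unique(as.integer(folds)))) {
    tr <- which(folds != f); te <- which(folds == f)
    fc$seed <- final_config$seed + f
    m <- train_final(enriched[tr, , drop = FALSE], y[tr], fc)
    oof[te] <- predict_final(m, enriched[te, , drop = FALSE])$probabilities
    final_fold_models[[as.character(f)]] <- m
    final_train_ids[[as.character(f)]] <- tr
  })
  report <- metric_report(scores = oof, truth = y,
                          threshold = final_config$threshold)
  final <- stage("final_refit", train_final(enriched, y, final_config))
  manifest <- list(
    package = as.character(utils::packageVersion("mc4deep")),
    n = length(y), n_pos = sum(y == 1L), n_neg = sum(y == 0L),
    k = as.integer(k), seed = as.integer(seed),
    net_config = unclass(net_config), final_config = unclass(final_config),
    max_iter = as.integer(max_iter), tol = tol,
    enriched_cols = ncol(enriched),
    stack_history = attr(enriched, "history"),
    stack_winners = vapply(attr(enriched, "provenance"), `[[`, "", "winner"),
    stop_reason = attr(enriched, "stop_reason"))
  manifest$config_hash <- fnv1a(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                                 digits = NA))
  run <- structure(list(report = report, oof_probs = oof, bundle = bundle,
                        enriched = enriched, final = final,
                        final_fold_models = final_fold_models,
                        final_train_ids = final_train_ids,
                        folds = folds, samples = samples, manifest = manifest),
                   class = "mc4_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.mc4_run <- function(x, ...) {
  cat("<mc4_run> n=", x$manifest$n, ", k=", x$manifest$k,
      ", enriched width=", x$manifest$enriched_cols, "\nheld-out ", sep = "")
  print(x$report)
  invisible(x)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rep <- run$report
  jsonlite::write_json(c(rep[c("SN", "SP", "ACC", "MCC", "AUC")],
                         unclass(rep$counts)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_encoded(run$bundle$advanced, file.path(out_dir, "advanced.tsv"))
  write_encoded(unclass(run$enriched), file.path(out_dir, "enriched.tsv"))
  jsonlite::write_json(attr(run$enriched, "provenance"),
                       file.path(out_dir, "enriched_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  calls <- data.frame(id = run$samples$id, probability = run$oof_probs,
                      label = as.integer(run$oof_probs >= run$final$config$threshold))
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Predict 4mC sites for new windows with a fitted pipeline
#'
#' Applies the fitted stages in sequence: per-scheme encodings and refit
#' extractors, the stored stacking winner sequence, then the final net.
#'
#' @param run an `mc4_run` from [run_pipeline()].
#' @param samples an `mc4_samples` table of new windows.
#' @param threshold decision threshold.
#' @return data.frame `id`, `probability`, `label`.
#' @export
predict_sites <- function(run, samples,
                          threshold = run$final$config$threshold) {
  stopifnot(inherits(run, "mc4_run"), inherits(samples, "mc4_samples"))
  adv <- extract_advanced(samples, run$bundle)
  enr <- stack_apply(run$enriched, adv)
  pr <- predict_final(run$final, enr, threshold = threshold)
  data.frame(id = samples$id, probability = pr$probabilities,
             label = pr$labels)
}
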