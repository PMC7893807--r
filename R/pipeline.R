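# FNV-1a over a JSON rendering: a dependency-free content hash for run
# manifests (not cryptographic).
content_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full discovery pipeline
#'
#' Orchestrates CARS domain scoring, greedy signature search, two-cluster
#' subtyping, kNN fitting with LOOCV (reported for k in 1, 3, 5, 7),
#' alpha diversity and ordination, and the between-subtype statistical
#' profile. With `out_dir` set, all artifacts (signature, assignment,
#' serialized model, diversity and distance tables, consolidated report,
#' run manifest) are written in the package's text formats; artifacts are
#' byte-identical across reruns with the same inputs and seed.
#'
#' @param abundance An `abundance_table` (counts or relative).
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param brain Optional samples x regions brain volume matrix.
#' @param tree Optional genus phylogeny for Faith PD.
#' @param pool,target_size Signature search parameters (defaults 30, 12).
#' @param k kNN neighborhood size (default 3).
#' @param distance kNN distance, `"bray_curtis"` or `"euclidean"`.
#' @param B Permutations per test (default 5000).
#' @param seed Global seed fanned out to stage substreams.
#' @param opposite_pair Optional two genus ids for the dominance-flip test.
#' @param out_dir Optional artifact directory.
#' @return Report list: `signature`, `assignment`, `model`, `loocv`,
#'   `diversity`, `profile`, `manifest` (plus `opposite_pattern` if a pair
#'   was given).
#' @export
run_discovery <- function(abundance, metadata, brain = NULL, tree = NULL,
                          pool = 30, target_size = 12, k = 3,
                          distance = c("bray_curtis", "euclidean"),
                          B = 5000, seed = 1, opposite_pair = NULL,
                          out_dir = NULL) {
  distance <- match.arg(distance)
  stopifnot(inherits(abundance, "abundance_table"))
  miss <- setdiff(rownames(abundance), metadata$sample_id)
  if (length(miss) > 0)
    stop("stage cars_scoring: metadata missing sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
    message(sprintf("[gutsig] stage %-12s n=%d elapsed=%.2fs", name,
                    nrow(abundance), proc.time()[["elapsed"]] - t0))
    out
  }

  sig <- stage("signature",
               greedy_search(abundance, metadata, pool = pool,
                             target_size = target_size))
  assignment <- stage("subtyping",
                      cluster_subtypes(abundance, sig$selected_genera,
                                       metadata))
  model <- stage("knn",
                 fit_knn(abundance, sig$selected_genera, assignment,
                         k = k, distance = distance))
  loocv <- stage("loocv", {
    ks <- unique(c(k, 1, 3, 5, 7))
    ks <- ks[ks + 1 <= nrow(abundance)]
    res <- lapply(ks, function(kk)
      loocv_accuracy(abundance, sig$selected_genera, assignment, k = kk,
                     distance = distance))
    names(res) <- paste0("k", ks)
    res
  })
  diversity <- stage("diversity", {
    dm <- bray_curtis(abundance, genera = sig$selected_genera)
    alpha <- alpha_diversity(abundance, tree = tree)
    list(alpha = alpha,
         distance = dm,
         pcoa = pcoa(dm, n_axes = min(2, nrow(abundance) - 1)),
         alpha_by_subtype = local({
           lab <- assignment$labels[alpha$sample_id]
           metrics <- setdiff(names(alpha), "sample_id")
           tests <- lapply(metrics, function(mtr)
             kruskal_wallis_perm(alpha[[mtr]], lab, B = B,
                                 seed = substream_seed(seed,
                                                       paste0("alpha.", mtr))))
           names(tests) <- metrics
           tests
         }))
  })
  profile <- stage("stats",
                   group_profile(metadata, assignment, brain = brain,
                                 B = B, seed = substream_seed(seed, "profile")))
  report <- list(signature = list(selected_genera = sig$selected_genera,
                                  objective_trace = sig$objective_trace,
                                  truncated = sig$truncated),
                 assignment = list(labels = as.list(assignment$labels),
                                   sizes = as.list(table(assignment$labels))),
                 loocv = lapply(loocv, function(l)
                   list(accuracy = l$accuracy, k = l$k)),
                 alpha_tests = diversity$alpha_by_subtype,
                 profile = profile,
                 manifest = list(
                   seed = seed, B = B, k = k, distance = distance,
                   pool = pool, target_size = target_size,
                   n_samples = nrow(abundance), n_genera = ncol(abundance),
                   package_version = as.character(
                     utils::packageVersion("gutsig")),
                   input_hash = content_hash(list(
                     a = round(unclass(abundance), 10),
                     m = metadata$sample_id, c = metadata$cars_total))))
  report$manifest$config_hash <- content_hash(report$manifest)
  if (!is.null(opposite_pair)) {
    report$opposite_pattern <- stage("opposite_pattern",
      opposite_pattern_test(abundance, opposite_pair[1], opposite_pair[2],
                            assignment))
  }

  result <- list(signature = sig, assignment = assignment, model = model,
                 loocv = loocv, diversity = diversity, profile = profile,
                 report = report, manifest = report$manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signature(sig, file.path(out_dir, "signature.tsv"))
    utils::write.table(
      data.frame(sample_id = names(assignment$labels),
                 subtype = assignment$labels),
      file.path(out_dir, "assignment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_knn_model(model, file.path(out_dir, "knn_model.json"))
    utils::write.table(diversity$alpha,
                       file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_distance_matrix(diversity$distance,
                          file.path(out_dir, "bray_curtis.tsv"))
    utils::write.table(
      data.frame(sample_id = rownames(diversity$pcoa$coordinates),
                 diversity$pcoa$coordinates, check.names = FALSE),
      file.path(out_dir, "pcoa.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_results(report, file.path(out_dir, "report"))
    jsonlite::write_json(report$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Classify a new cohort with a trained kNN model
#'
#' Assigns subtypes to new samples; genera of the signature missing from
#' the new table are imputed as zero with a per-genus warning, but more
#' than half missing is a hard error. With metadata supplied, the
#' between-subtype statistical profile is rerun on the new cohort.
#'
#' @param model A `knn_model` (object or path to a serialized model).
#' @param abundance New cohort `abundance_table`.
#' @param metadata Optional metadata for the new cohort.
#' @param brain Optional brain volume matrix.
#' @param B,seed Permutation settings for the profile.
#' @param out_dir Optional artifact directory.
#' @return List: `labels`, `sizes`, and `profile` when metadata was given.
#' @export
run_classify <- function(model, abundance, metadata = NULL, brain = NULL,
                         B = 5000, seed = 1, out_dir = NULL) {
  if (is.character(model)) model <- read_knn_model(model)
  stopifnot(inherits(model, "knn_model"),
            inherits(abundance, "abundance_table"))
  absent <- setdiff(model$signature, colnames(abundance))
  if (length(absent) > length(model$signature) / 2)
    stop(sprintf("%d of %d signature genera absent from new table",
                 length(absent), length(model$signature)), call. = FALSE)
  labels <- predict(model, abundance)
  out <- list(labels = labels, sizes = table(labels))
  if (!is.null(metadata)) {
    out$profile <- group_profile(metadata, labels, brain = brain, B = B,
                                 seed = substream_seed(seed, "profile"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(sample_id = names(labels), subtype = labels),
      file.path(out_dir, "assignment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(out$profile))
      write_results(out$profile, file.path(out_dir, "report"))
  }
  out
}
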