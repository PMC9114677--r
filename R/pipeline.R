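#' Run the full comparison pipeline from a configuration
#'
#' Executes cross-validated fusion comparison from a single declarative
#' configuration (a YAML file path or an equivalent nested list), writing a
#' tidy per-fold results CSV, a JSON summary and a manifest capturing every
#' resolved default and seed — enough to reproduce the run byte for byte.
#'
#' Configuration schema (all blocks optional except `dataset`):
#' \preformatted{
#' dataset:
#'   path: table.csv          # delimited table, or instead:
#'   synthetic: {n: 300, classes: 3, features: 5, separation: 8, seed: 1}
#'   label: class
#'   delim: ","
#' preprocess: {normalize: true, pca_retain: ~}
#' base_classifiers:          # optional; default = the standard five
#'   - {kind: knn, k: 10, seed: 3}
#' fusion: {delta: 0.9, epochs: 100, regime: benchmark}
#' methods: [bitfusion, majority]
#' cv: {k: 10, stratified: true, seed: 1}
#' output: out/
#' }
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return The `"fusion_cv"` result, invisibly. Artifacts are written under
#'   the configured output directory: `results.csv`, `summary.json`,
#'   `manifest.json`, `fusion_model.json` (when bit-fusion is among the
#'   methods, trained on the full dataset).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("config must be a YAML path or a list")
  if (is.null(cfg$dataset)) abort("config field 'dataset' is required")
  label <- cfg$dataset$label %||% "class"

  if (!is.null(cfg$dataset$path)) {
    data <- load_table(cfg$dataset$path, label = label,
                       delim = cfg$dataset$delim %||% ",")
  } else if (!is.null(cfg$dataset$synthetic)) {
    s <- cfg$dataset$synthetic
    data <- make_gaussian_dataset(n = s$n %||% 300L,
                                  classes = s$classes %||% 3L,
                                  features = s$features %||% 5L,
                                  separation = s$separation %||% 4,
                                  seed = s$seed %||% 1L)
    label <- "class"
  } else {
    abort("config field 'dataset' needs either 'path' or 'synthetic'")
  }

  cvc <- cfg$cv %||% list()
  seed <- cvc$seed %||% 1L
  methods <- unlist(cfg$methods %||% c("bitfusion", "majority"))
  known <- c("bitfusion", fusion_method_names())
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) {
    abort(sprintf("config field 'methods' contains unknown method(s): %s",
                  paste(bad, collapse = ", ")))
  }

  specs <- if (is.null(cfg$base_classifiers)) {
    default_base_specs(seed = derive_seed(seed, 5L))
  } else {
    purrr::map(cfg$base_classifiers, function(b) {
      if (is.null(b$kind)) abort("each base_classifiers entry needs a 'kind'")
      hp <- b[setdiff(names(b), c("kind", "seed"))]
      do.call(base_spec, c(list(method = b$kind, seed = b$seed %||% 1L), hp))
    })
  }

  fus <- cfg$fusion %||% list()
  fconfig <- fusion_config(delta = fus$delta %||% 0.9,
                           eta = fus$eta, mu = fus$mu,
                           epochs = fus$epochs %||% 100L,
                           seed = fus$seed %||% derive_seed(seed, 9L),
                           error_sign = fus$error_sign,
                           regime = fus$regime %||% "benchmark")

  pre <- cfg$preprocess %||% list()
  cv <- cross_validate(data, label = label, specs = specs, methods = methods,
                       k = cvc$k %||% 10L, config = fconfig,
                       normalize = pre$normalize %||% TRUE,
                       pca_retain = pre$pca_retain,
                       stacking = cfg$stacking %||% "out_of_fold",
                       stratified = cvc$stratified %||% TRUE, seed = seed)

  outdir <- cfg$output %||% "bitfusion-run"
  write_cv_results(cv, outdir)
  if ("bitfusion" %in% methods) {
    built <- build_xi(data, label = label, specs = specs,
                      stacking = cfg$stacking %||% "out_of_fold",
                      seed = derive_seed(seed, 2L))
    model <- train_bitfusion(built$xi, built$labels, fconfig)
    write_fusion_model(model, file.path(outdir, "fusion_model.json"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("bitfusion")),
    dataset = cfg$dataset, label = label,
    n_instances = nrow(data), class_set = levels(data[[label]]),
    preprocess = list(normalize = pre$normalize %||% TRUE,
                      pca_retain = pre$pca_retain),
    base_classifiers = purrr::map(specs, unclass),
    fusion = unclass(fconfig), methods = methods,
    cv = list(k = cvc$k %||% 10L, stratified = cvc$stratified %||% TRUE,
              seed = seed),
    stacking = cfg$stacking %||% "out_of_fold",
    fallback_stage_counts = if (!is.null(cv$fallback_stages)) {
      cv$fallback_stages |>
        dplyr::group_by(.data$stage) |>
        dplyr::summarise(n_instances = sum(.data$n_instances), .groups = "drop")
    }
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(cv)
}

#' Write a synthetic study to disk
#'
#' Generates a Gaussian feature table and/or a raw support tensor from a
#' synthetic spec and writes them as plain-text files (CSV plus a JSON
#' sidecar for the tensor).
#'
#' @param dir Output directory (created if needed).
#' @param n,classes,features,separation Passed to [make_gaussian_dataset()].
#' @param classifiers,base_accuracies,correlation,mode Passed to
#'   [make_synthetic_xi()]; set `classifiers = 0` to skip the tensor.
#' @param seed Integer seed.
#' @return Paths written, invisibly.
#' @export
simulate_study <- function(dir, n = 300L, classes = 3L, features = 5L,
                           separation = 4, classifiers = 5L,
                           base_accuracies = 0.7, correlation = 0,
                           mode = "soft", seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  data <- make_gaussian_dataset(n, classes, features, separation, seed)
  dpath <- file.path(dir, "dataset.csv")
  write_table(data, dpath)
  paths <- dpath
  if (classifiers > 0L) {
    sim <- make_synthetic_xi(n, classes, classifiers, base_accuracies,
                             correlation, mode = mode, seed = derive_seed(seed, 3L))
    xpath <- file.path(dir, "support_tensor.csv")
    write_xi(sim$xi, xpath)
    readr::write_csv(tibble::tibble(instance = seq_along(sim$labels),
                                    class = as.character(sim$labels)),
                     file.path(dir, "labels.csv"))
    paths <- c(paths, xpath, file.path(dir, "labels.csv"))
  }
  invisible(paths)
}
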