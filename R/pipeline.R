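# Pipeline orchestration: YAML configuration, staged execution and
# provenance manifests.

pkg_version <- function() {
  as.character(utils::packageVersion("ctibench"))
}

file_digest <- function(path) unname(tools::md5sum(path))

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  file_digest(tmp)
}

#' Default pipeline configuration
#'
#' All domain thresholds live here with their benchmark defaults: KiBA hit
#' score 3, Kd hit threshold 10 uM, maximum sequence length 1400, maximum
#' SMILES length 348, LRB rotatable-bond cap 10, RRB fraction cap 0.184,
#' 10 folds.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_compounds = 30, n_targets = 20, n_pairs = 150,
                    prevalence = 0.289, label_noise = 0,
                    mutant_fraction = 0, measure = "KIBA_SCORE"),
    preprocess = list(max_seq_len = 1400, max_smiles_len = 348,
                      kiba_max_hit = 3, kd_um_hit = 10),
    filter = list(lrb_max_rotatable = 10, rrb_max_rbf = 0.184),
    split = list(scenario = "warm-compound", n_folds = 3),
    train = list(learning_rate = 0.01, momentum = 0.9, batch_size = 32,
                 epochs = 5)
  )
}

validate_config <- function(config) {
  known_scen <- c("warm-compound", "warm-target", "cold-compound",
                  "cold-target", "mutation-aware")
  bad <- character(0)
  if (!is.numeric(config$seed)) bad <- c(bad, "seed")
  if (!is.null(config$split$scenario) &&
      !(config$split$scenario %in% known_scen)) {
    bad <- c(bad, paste0("split.scenario (", config$split$scenario,
                         "; known: ", paste(known_scen, collapse = ", "), ")"))
  }
  if (!is.null(config$simulate$label_noise) &&
      (config$simulate$label_noise < 0 || config$simulate$label_noise >= 0.5)) {
    bad <- c(bad, "simulate.label_noise")
  }
  if (length(bad) > 0) {
    stop("invalid configuration key(s): ", paste(bad, collapse = "; "))
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown scenario names and out-of-range values are rejected with the
#' offending keys listed. Missing sections fall back to
#' [default_config()].
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), user)
  validate_config(config)
  config
}

#' Run the benchmark pipeline on synthetic data
#'
#' Executes the stages in order: simulate (generate compounds, targets,
#' interactions), preprocess (length/validity filters, dedup), split
#' (fold construction under the configured scenario), featurize (2D
#' fingerprints and physicochemical target vectors), train + evaluate
#' (two-tower dense model, cross-validated). Every stage writes its
#' artifact under `out_dir`, and a run manifest captures the package
#' version, configuration digest, seeds, input digests and per-stage
#' record counts.
#'
#' @param config Configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created if absent).
#' @param stages Stages to run, in order (default all).
#' @return The manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "preprocess", "split",
                                    "featurize", "train")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(toolkit_version = pkg_version(),
                   config_digest = config_digest(config),
                   seed = config$seed,
                   stages = list())
  seed <- config$seed

  records <- NULL
  ds <- NULL
  if ("simulate" %in% stages) {
    sim <- config$simulate
    ds <- synthetic_dataset(
      n_compounds = sim$n_compounds, n_targets = sim$n_targets,
      n_pairs = sim$n_pairs, mutant_fraction = sim$mutant_fraction,
      prevalence = sim$prevalence, label_noise = sim$label_noise,
      measure = sim$measure, seed = seed)
    records <- ds$records
    tab_path <- file.path(out_dir, "interactions.tsv")
    write_interaction_table(records, tab_path)
    write_compounds_smi(ds$compounds, file.path(out_dir, "compounds.smi"))
    write_targets_fasta(
      stats::setNames(ds$targets$sequence, ds$targets$target_id),
      file.path(out_dir, "targets.fasta"))
    manifest$stages$simulate <- list(
      n_records = nrow(records),
      digest = file_digest(tab_path))
  }
  if ("preprocess" %in% stages) {
    if (is.null(records)) {
      rd <- read_interaction_table(file.path(out_dir, "interactions.tsv"))
      records <- rd$records
    }
    pp <- preprocess_records(records,
                             max_seq_len = config$preprocess$max_seq_len,
                             max_smiles_len = config$preprocess$max_smiles_len)
    records <- pp$records
    write_exclusion_report(pp$report, file.path(out_dir, "exclusions.json"))
    write_interaction_table(records, file.path(out_dir, "interactions_clean.tsv"))
    manifest$stages$preprocess <- list(
      n_in = pp$report$n_in, n_kept = pp$report$n_kept)
  }
  folds <- NULL
  if ("split" %in% stages) {
    scen <- config$split$scenario
    nf <- config$split$n_folds
    folds <- switch(scen,
      "warm-compound" = warm_split(records, "compound", nf, seed),
      "warm-target" = warm_split(records, "target", nf, seed),
      "cold-compound" = cold_split(records, "compound", nf),
      "cold-target" = cold_split(records, "target", nf),
      "mutation-aware" = NULL)
    if (scen == "mutation-aware") {
      ms <- mutation_split(records)
      write_interaction_table(ms$train, file.path(out_dir, "train.tsv"))
      write_interaction_table(ms$test, file.path(out_dir, "test.tsv"))
      manifest$stages$split <- list(scenario = scen,
                                    n_train = nrow(ms$train),
                                    n_test = nrow(ms$test))
    } else {
      write_fold_assignment(folds, file.path(out_dir, "folds.tsv"))
      manifest$stages$split <- list(scenario = scen, n_folds = nf,
                                    sizes = tabulate(folds$fold_of, nf))
    }
  }
  features <- NULL
  if ("featurize" %in% stages) {
    smi <- stats::setNames(records$smiles, records$compound_id)
    uniq <- !duplicated(names(smi))
    fp <- encode_2dfp(smi[uniq])
    proj <- fit_physchem_pca(synthetic_aa_properties(seed = seed))
    useq <- records[!duplicated(records$target_id),
                    c("target_id", "sequence")]
    tmat <- t(vapply(useq$sequence, function(s) {
      m <- encode_physchem(s, proj)
      colMeans(m[seq_len(attr(m, "true_length")), , drop = FALSE])
    }, numeric(20)))
    rownames(tmat) <- useq$target_id
    features <- list(compound_fp = fp, target_physchem = tmat,
                     projection = proj)
    manifest$stages$featurize <- list(
      n_compounds = nrow(fp), n_targets = nrow(tmat),
      fp_width = ncol(fp))
  }
  if ("train" %in% stages) {
    if (is.null(features) || is.null(folds)) {
      stop("the train stage needs the featurize and split stages ",
           "(or their artifacts); run those first")
    }
    Xc <- features$compound_fp[records$compound_id, , drop = FALSE]
    Xt <- features$target_physchem[records$target_id, , drop = FALSE]
    y <- records$label
    cfg <- train_config(learning_rate = config$train$learning_rate,
                        momentum = config$train$momentum,
                        batch_size = config$train$batch_size,
                        epochs = config$train$epochs, seed = seed)
    factory <- function() cti_model(fp_mlp_params(seed),
                                    embedding_mlp_params(20, seed),
                                    seed = seed)
    cv <- cross_validate(Xc, Xt, y, folds, factory, cfg)
    utils::write.table(cv$aggregate, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$train <- list(
      aggregate = stats::setNames(as.list(cv$aggregate$mean),
                                  cv$aggregate$metric))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
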