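#' Run the full evaluation pipeline
#'
#' Executes simulate (or load) -> depurate -> connect -> nonparametric
#' screen -> REML (genotype-inclusive and -exclusive) -> BLUP for both
#' models -> selection index -> model comparison, writing one TSV per stage
#' plus a JSON manifest (seed, config hash, tolerances, convergence
#' diagnostics, per-stage timings) into `out_dir`. Outputs are deterministic
#' given the config seed.
#'
#' @param config A [sim_config()] describing the simulation block, or a
#'   list with `pedigree_csv` and `records_csv` paths for real inputs
#'   (exactly one of the two forms).
#' @param out_dir Output directory (created if needed).
#' @param traits Traits to evaluate (default all four).
#' @param reml_tol,reml_max_iter REML convergence controls.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, out_dir, traits = c("milk", "fat", "protein", "dm"),
                         reml_tol = 1e-12, reml_max_iter = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  is_sim <- inherits(config, "sim_config")
  if (!is_sim && !all(c("pedigree_csv", "records_csv") %in% names(config))) {
    stop("config must be a sim_config or carry pedigree_csv + records_csv paths")
  }
  hash <- config_hash(config)
  tsv <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    message("stage ", name, " done (", timings[[name]], "s)")
    res
  }

  sim <- stage("simulate", {
    if (is_sim) {
      ped <- simulate_pedigree(config)
      simulate_lactation_dataset(ped, NULL, config)
    } else {
      ped <- read_pedigree_csv(config$pedigree_csv)
      recs <- utils::read.csv(config$records_csv, stringsAsFactors = FALSE)
      list(pedigree = ped, records = recs, tbv = NULL, genotypes = NULL)
    }
  })
  ped <- sim$pedigree
  tsv(sim$records, "01_records_raw")

  dep <- stage("depurate", depurate_records(sim$records))
  tsv(dep$rejections, "02_depuration_log")
  conn <- stage("connect", connect_to_pedigree(dep$records, ped))
  records <- conn$records
  tsv(records, "03_records_analysis")

  screen <- stage("screen", factor_screen(
    records, paste0(traits, "_kg"),
    intersect(c("farm", "year", "month", "season", "birth_type",
                "genotype_class"), names(records))))
  tsv(screen, "04_nonparametric_screen")

  Ainv <- a_inverse_sparse(ped)
  fits <- list(); sols <- list(); evals <- list()
  fit_rows <- list()
  for (variant in c("incl_genotype", "excl_genotype")) {
    inc <- variant == "incl_genotype"
    for (tr in traits) {
      sp <- model_spec(tr, include_genotype = inc)
      dm <- build_design_matrices(records, sp, ped)
      fit <- stage(paste0("reml_", variant, "_", tr),
                   reml_fit(dm, Ainv, tol = reml_tol,
                            max_iter = reml_max_iter))
      sol <- stage(paste0("blup_", variant, "_", tr),
                   solve_blup(dm, Ainv, fit$vc))
      key <- paste0(variant, ".", tr)
      fits[[key]] <- fit; sols[[key]] <- sol
      ev <- evaluation_table(sol, ped, records)
      ev$trait <- tr; ev$model_variant <- variant
      evals[[key]] <- ev
      fit_rows[[key]] <- data.frame(
        model_variant = variant, trait = tr,
        sigma_a2 = fit$vc[["sigma_a2"]], sigma_p2 = fit$vc[["sigma_p2"]],
        sigma_pe2 = fit$vc[["sigma_pe2"]], sigma_e2 = fit$vc[["sigma_e2"]],
        h2 = fit$h2, h2_se = if (is.null(fit$h2_se)) NA_real_ else fit$h2_se,
        repeatability = fit$repeatability,
        converged = fit$converged, iterations = fit$iterations,
        stringsAsFactors = FALSE)
    }
  }
  tsv(do.call(rbind, fit_rows), "05_variance_components")
  tsv(do.call(rbind, evals), "06_evaluations")

  ico <- NULL
  if (all(c("milk", "fat", "protein") %in% traits)) {
    ico <- stage("ico", {
      pbv_tab <- data.frame(animal_id = ped$ped$animal_id)
      for (tr in c("milk", "fat", "protein")) {
        pbv_tab[[tr]] <- unname(sols[[paste0("incl_genotype.", tr)]]$pbv)
      }
      does <- pbv_tab[ped$ped$sex == "doe", , drop = FALSE]
      sc <- ico_scores(does)
      nl <- min(236L, floor(nrow(sc) / 3))
      nm <- min(238L, nrow(sc) - 2L * nl)
      rank_stratified_sample(sc, n_low = nl, n_mid = nm, n_high = nl)
    })
    tsv(ico, "07_ico_ranking")
  }

  comp <- stage("compare", {
    rows <- lapply(traits, function(tr) {
      cm <- compare_models(sols[[paste0("incl_genotype.", tr)]],
                           sols[[paste0("excl_genotype.", tr)]],
                           ped, doe_ids = records$doe_id)
      cm$trait <- tr
      cm
    })
    do.call(rbind, rows)
  })
  tsv(comp, "08_model_comparison")

  manifest <- list(
    package_version = as.character(utils::packageVersion("caprigen")),
    r_version = as.character(getRversion()),
    config_hash = hash,
    seed = if (is_sim) config$seed else NA,
    reml_tol = reml_tol, reml_max_iter = reml_max_iter,
    convergence = lapply(fits, function(f)
      list(converged = f$converged, iterations = f$iterations,
           criterion = f$criterion)),
    stage_timings_s = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, records = records, screen = screen, fits = fits,
                 solutions = sols, evaluations = evals, ico = ico,
                 comparison = comp, manifest = manifest))
}

# small polynomial rolling hash of the deparsed config; stable across
# sessions for the same configuration values
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
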