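#' Configuration of a full method-comparison run
#'
#' @param methods subset of `c("GMB", "GMS", "TRU", "TRA")`: body-landmark,
#'   scale-landmark, truss-distance and caliper-distance methods.
#' @param design a [design_spec()] for synthetic input.
#' @param effects an [effect_spec()] for synthetic input.
#' @param inputs optional named list mapping a method to an input file
#'   (`.tps` or `.csv` for GMB/GMS, `.csv` for TRU/TRA); methods without an
#'   entry are generated synthetically.
#' @param n_perm_mantel permutations per Mantel test.
#' @param n_perm_permanova permutations per PERMANOVA / detachment test.
#' @param alpha significance level used throughout.
#' @param seed mandatory master seed; every stochastic stage derives its own
#'   sub-stream from it.
#' @param out_dir optional output directory for the report CSVs.
#' @param allometry_pooling grouping for the allometric exponent fits within
#'   each species (default `"site"`).
#' @param size_pooling grouping for the shape-on-size regression (default
#'   `"species"`).
#' @param scale_characteristic logical vector, recycled to `n_species`:
#'   which species have a characteristic scale shape (GMS only).
#' @param verbose emit stage-level progress messages with record counts.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(methods = c("GMB", "GMS", "TRU", "TRA"),
                            design = design_spec(), effects = effect_spec(),
                            inputs = NULL,
                            n_perm_mantel = 999, n_perm_permanova = 9999,
                            alpha = 0.05, seed, out_dir = NULL,
                            allometry_pooling = "site",
                            size_pooling = "species",
                            scale_characteristic = FALSE,
                            verbose = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(methods = methods, design = design, effects = effects,
                 inputs = inputs, n_perm_mantel = n_perm_mantel,
                 n_perm_permanova = n_perm_permanova, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir,
                 allometry_pooling = allometry_pooling,
                 size_pooling = size_pooling,
                 scale_characteristic = scale_characteristic,
                 verbose = verbose),
            class = "pipeline_config")
}

.is_landmark_method <- function(m) m %in% c("GMB", "GMS")

.load_method_data <- function(config, method) {
  inp <- config$inputs[[method]]
  if (!is.null(inp)) {
    if (.is_landmark_method(method)) {
      if (grepl("\\.tps$", inp, ignore.case = TRUE))
        return(read_landmarks_tps(inp))
      return(read_landmark_csv(inp))
    }
    return(read_distance_csv(inp))
  }
  d <- config$design
  d$seed <- stage_seed(config$seed, paste0("generate/", method))
  switch(method,
         GMB = generate_landmarks(d, config$effects, template = "body"),
         GMS = generate_landmarks(d, config$effects, template = "scale",
                                  characteristic = config$scale_characteristic),
         TRU = generate_distances(d, config$effects, mode = "truss"),
         TRA = generate_distances(d, config$effects, mode = "caliper"))
}

#' Run the full morphometric method comparison
#'
#' For every requested method and species: removes size (Procrustes fit and
#' shape-on-logCS regression for landmark methods; Elliott allometric
#' standardization with the SL-decorrelation recheck for distance methods),
#' computes the repeatability and reproducibility Mantel tables, selects one
#' random repeat per individual and measurer, and runs per-measurer
#' canonical variate analyses (grouping by site) and the two-way
#' site-by-measurer PERMANOVA.  Concordance tables are then pooled across
#' species and methods into the hierarchical Kruskal-Wallis level
#' comparisons.  All randomness derives from `config$seed` via named
#' sub-streams, so a rerun with the same configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `"morphorep_report"`: per-method results
#'   (standardized data / residuals, concordance tables, per-species
#'   `cva` and `permanova` objects), pooled concordance tables, level
#'   comparisons, and a run `manifest`.  Written to `config$out_dir` when
#'   set (see [write_report()]).
#' @export
#' @examples
#' cfg <- pipeline_config(methods = "TRU",
#'                        design = design_spec(n_species = 1,
#'                                             n_individuals = 6),
#'                        n_perm_mantel = 49, n_perm_permanova = 99,
#'                        seed = 1, verbose = FALSE)
#' rep <- run_pipeline(cfg)
#' rep$levels$repeatability_by_species$summary
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  methods <- config$methods
  results <- list()
  rep_tables <- list(); repro_tables <- list()

  for (method in methods) {
    data <- .load_method_data(config, method)
    say("[%s] input: %d records, %d measurement values", method, nrow(data),
        n_measurements(data))
    species <- sort(unique(data$species))
    per_species <- list()
    for (sp in species) {
      sub <- .subset_dataset(data, data$species == sp)
      if (.is_landmark_method(method)) {
        fit <- procrustes_fit(sub)
        analysed <- regress_out_size(fit, pooling = config$size_pooling)
        decorr <- NULL
        say("[%s/%s] Procrustes fit: %d configurations, %d iterations",
            method, sp, nrow(fit$aligned), fit$iterations)
      } else {
        mod <- fit_allometry(sub, pooling = config$allometry_pooling)
        analysed <- standardize(sub, mod)
        decorr <- recheck_decorrelation(analysed, alpha = config$alpha)
        say("[%s/%s] allometric standardization: b in [%.2f, %.2f], %d/%d variables size-free",
            method, sp, min(mod$b), max(mod$b),
            sum(decorr$pass, na.rm = TRUE), nrow(decorr))
      }
      ct_rep <- concordance(analysed, "repeatability",
                            n_perm = config$n_perm_mantel,
                            seed = stage_seed(config$seed,
                                              paste("mantel", method, sp)),
                            method = method)
      ct_repro <- concordance(analysed, "reproducibility",
                              n_perm = config$n_perm_mantel,
                              seed = stage_seed(config$seed,
                                                paste("mantel", method, sp)),
                              method = method)
      say("[%s/%s] concordance: %d repeatability, %d reproducibility pairs",
          method, sp, nrow(ct_rep), nrow(ct_repro))
      am <- select_random_repeat(analysed,
                                 seed = stage_seed(config$seed,
                                                   paste("select", method,
                                                         sp)))
      cvas <- list()
      for (m in sort(unique(am$labels$measurer))) {
        sel <- am$labels$measurer == m
        sub_am <- structure(list(labels = am$labels[sel, , drop = FALSE],
                                 values = am$values[sel, , drop = FALSE]),
                            class = "analysis_matrix")
        cvas[[m]] <- cva(sub_am, grouping = "site",
                         n_perm = config$n_perm_permanova,
                         seed = stage_seed(config$seed,
                                           paste("cva", method, sp, m)),
                         alpha = config$alpha)
      }
      pm <- permanova(am, factors = c("site", "measurer"),
                      n_perm = config$n_perm_permanova,
                      seed = stage_seed(config$seed,
                                        paste("permanova", method, sp)))
      say("[%s/%s] separation: %d specimens; F(site) = %.2f, F(measurer) = %.2f",
          method, sp, nrow(am$values), pm$table$F[1], pm$table$F[2])
      per_species[[sp]] <- list(analysed = analysed, decorrelation = decorr,
                                repeatability = ct_rep,
                                reproducibility = ct_repro,
                                analysis_matrix = am, cva = cvas,
                                permanova = pm)
      rep_tables[[paste(method, sp)]] <- ct_rep
      repro_tables[[paste(method, sp)]] <- ct_repro
    }
    results[[method]] <- per_species
  }

  rep_all <- do.call(rbind, lapply(rep_tables, as.data.frame))
  repro_all <- do.call(rbind, lapply(repro_tables, as.data.frame))
  rownames(rep_all) <- rownames(repro_all) <- NULL
  levels_out <- list()
  n_species <- length(unique(rep_all$species))
  n_measurers <- length(unique(rep_all$measurer_a))
  if (n_measurers > 1)
    levels_out$repeatability_by_measurer <-
      group_and_compare(rep_all, "measurer", alpha = config$alpha)
  if (n_species > 1) {
    levels_out$repeatability_by_species <-
      group_and_compare(rep_all, "species", alpha = config$alpha)
    if (nrow(repro_all))
      levels_out$reproducibility_by_species <-
        group_and_compare(repro_all, "species", alpha = config$alpha)
  }
  if (length(methods) > 1) {
    levels_out$repeatability_by_method <-
      group_and_compare(rep_all, "method", alpha = config$alpha)
    if (nrow(repro_all))
      levels_out$reproducibility_by_method <-
        group_and_compare(repro_all, "method", alpha = config$alpha)
  }

  manifest <- list(
    package = "morphorep",
    version = as.character(utils::packageVersion("morphorep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    methods = methods,
    n_perm_mantel = config$n_perm_mantel,
    n_perm_permanova = config$n_perm_permanova,
    alpha = config$alpha,
    design = unclass(config$design),
    effects = lapply(unclass(config$effects), as.vector),
    inputs = if (is.null(config$inputs)) "synthetic" else config$inputs,
    repeatability_rows = nrow(rep_all),
    reproducibility_rows = nrow(repro_all))

  out <- structure(list(results = results, repeatability = rep_all,
                        reproducibility = repro_all, levels = levels_out,
                        manifest = manifest, config = config),
                   class = "morphorep_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' Write a pipeline report bundle as CSV files plus a manifest
#'
#' @param report a `morphorep_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "morphorep_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(report$repeatability, "repeatability.csv")
  wcsv(report$reproducibility, "reproducibility.csv")
  for (nm in names(report$levels)) {
    lv <- report$levels[[nm]]
    wcsv(lv$summary, paste0(nm, "_summary.csv"))
    wcsv(lv$pairwise, paste0(nm, "_pairwise.csv"))
  }
  perm_rows <- list(); detach_rows <- list()
  for (method in names(report$results)) {
    for (sp in names(report$results[[method]])) {
      r <- report$results[[method]][[sp]]
      tab <- r$permanova$table
      tab <- cbind(data.frame(method = method, species = sp), tab)
      names(tab) <- c("method", "species", "Source", "Sum of sqrs", "df",
                      "Mean square", "F", "p")
      perm_rows[[paste(method, sp)]] <- tab
      for (m in names(r$cva))
        detach_rows[[paste(method, sp, m)]] <-
          data.frame(method = method, species = sp, measurer = m,
                     detachment = r$cva[[m]]$detachment_class,
                     significant_pairs = r$cva[[m]]$n_significant_pairs)
    }
  }
  wcsv(do.call(rbind, perm_rows), "permanova.csv")
  wcsv(do.call(rbind, detach_rows), "cva_detachment.csv")
  yaml::write_yaml(report$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.morphorep_report <- function(x, ...) {
  cat("Morphometric method comparison report\n")
  cat(sprintf("  methods: %s; seed %d\n",
              paste(names(x$results), collapse = ", "), x$manifest$seed))
  cat(sprintf("  %d repeatability and %d reproducibility Mantel comparisons\n",
              nrow(x$repeatability), nrow(x$reproducibility)))
  if (!is.null(x$levels$repeatability_by_method)) {
    cat("  mean repeatability by method:\n")
    print(x$levels$repeatability_by_method$summary[c("group", "n", "mean",
                                                     "sd", "letter")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
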