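# Repeatability / reproducibility engine: matched specimen matrices,
# Euclidean distance matrices, pairwise Mantel tests, hierarchical grouping
# of R values and Kruskal-Wallis comparisons with a compact letter display.

#' Euclidean distance matrix between individuals
#'
#' @param m numeric matrix, one row per individual (>= 3), no missing
#'   values; row names identify individuals.
#' @return symmetric `n x n` matrix with zero diagonal,
#'   `d_ij = ||row_i - row_j||`.
#' @export
euclidean_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1, any)]
    if (is.null(bad)) bad <- which(apply(is.na(m), 1, any))
    stop("missing values for individual(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.matrix(stats::dist(m))
}

# normalize analysis inputs to list(labels = data.frame, values = matrix)
.analysis_frame <- function(x) {
  if (inherits(x, "shape_residuals"))
    return(list(labels = x$labels, values = x$variables))
  if (inherits(x, "distance_dataset"))
    return(list(labels = as.data.frame(x)[.label_cols],
                values = dd_values(x)))
  if (is.list(x) && all(c("labels", "values") %in% names(x)))
    return(list(labels = as.data.frame(x$labels),
                values = as.matrix(x$values)))
  stop("expected shape_residuals, a distance_dataset, or list(labels, values)",
       call. = FALSE)
}

#' Split an analysis set into matched per-dataset specimen matrices
#'
#' One "dataset" is the table of one measurer's repeat for one population:
#' all records sharing (species, site, measurer, repeat).  Rows are ordered
#' canonically by individual id so that matched datasets align row-for-row.
#' The design must be complete: every (species, site) must contain the same
#' individuals in every (measurer, repeat) cell.
#'
#' @param x a `shape_residuals`, a (standardized) `distance_dataset`, or a
#'   `list(labels, values)`.
#' @return a named list of `list(individual_ids, values)` keyed
#'   `species|site|measurer|repeat`, with attribute `cells` (data frame of
#'   the key columns).
#' @export
specimen_matrices <- function(x) {
  af <- .analysis_frame(x)
  lab <- af$labels
  key <- do.call(paste, c(lab[c("species", "site", "measurer", "repeat")],
                          list(sep = "|")))
  .check_complete(lab)
  out <- list()
  cells <- unique(lab[c("species", "site", "measurer", "repeat")])
  cells <- cells[order(cells$species, cells$site, cells$measurer,
                       cells[["repeat"]]), , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    kk <- paste(cells$species[i], cells$site[i], cells$measurer[i],
                cells[["repeat"]][i], sep = "|")
    rows <- which(key == kk)
    ord <- order(lab$individual[rows])
    rows <- rows[ord]
    v <- af$values[rows, , drop = FALSE]
    rownames(v) <- lab$individual[rows]
    out[[kk]] <- list(individual_ids = lab$individual[rows], values = v)
  }
  structure(out, cells = cells, class = "specimen_matrices")
}

# completeness of the crossed design; errors list the missing cells
.check_complete <- function(lab) {
  pops <- unique(lab[c("species", "site")])
  meas <- sort(unique(lab$measurer))
  reps <- sort(unique(lab[["repeat"]]))
  missing <- character(0)
  for (i in seq_len(nrow(pops))) {
    sel <- lab$species == pops$species[i] & lab$site == pops$site[i]
    inds <- sort(unique(lab$individual[sel]))
    for (m in meas) for (r in reps) {
      got <- sort(lab$individual[sel & lab$measurer == m &
                                   lab[["repeat"]] == r])
      if (!identical(got, inds))
        missing <- c(missing, paste(pops$species[i], pops$site[i], m, r,
                                    sep = "|"))
    }
  }
  if (length(missing))
    stop("incomplete design; missing or mismatched cells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Enumerate the dataset pairs compared at a concordance mode
#'
#' Repeatability compares the repeats of one measurer on one population:
#' `choose(n_repeats, 2)` pairs per (species, site, measurer).
#' Reproducibility compares datasets of different measurers on one
#' population: `choose(n_measurers, 2) * n_repeats^2` pairings per
#' (species, site) — every repeat of one measurer against every repeat of
#' the other.
#'
#' @param x input accepted by [specimen_matrices()], or a `specimen_matrices`
#'   object.
#' @param mode `"repeatability"` or `"reproducibility"`.
#' @return data frame with columns `species`, `site`, `measurer_a`,
#'   `repeat_a`, `measurer_b`, `repeat_b` (zero rows when no pairs exist,
#'   e.g. a single measurer in reproducibility mode).
#' @export
enumerate_pairs <- function(x, mode = c("repeatability", "reproducibility")) {
  mode <- match.arg(mode)
  cells <- if (inherits(x, "specimen_matrices")) attr(x, "cells") else
    attr(specimen_matrices(x), "cells")
  pops <- unique(cells[c("species", "site")])
  meas <- sort(unique(cells$measurer))
  reps <- sort(unique(cells[["repeat"]]))
  rows <- list()
  for (i in seq_len(nrow(pops))) {
    if (mode == "repeatability") {
      for (m in meas) {
        if (length(reps) < 2) next
        cmb <- utils::combn(reps, 2)
        for (j in seq_len(ncol(cmb)))
          rows[[length(rows) + 1L]] <-
            data.frame(species = pops$species[i], site = pops$site[i],
                       measurer_a = m, repeat_a = cmb[1, j],
                       measurer_b = m, repeat_b = cmb[2, j])
      }
    } else {
      if (length(meas) < 2) next
      cmb <- utils::combn(meas, 2)
      for (j in seq_len(ncol(cmb)))
        for (ra in reps) for (rb in reps)
          rows[[length(rows) + 1L]] <-
            data.frame(species = pops$species[i], site = pops$site[i],
                       measurer_a = cmb[1, j], repeat_a = ra,
                       measurer_b = cmb[2, j], repeat_b = rb)
    }
  }
  if (!length(rows))
    return(data.frame(species = character(0), site = character(0),
                      measurer_a = character(0), repeat_a = integer(0),
                      measurer_b = character(0), repeat_b = integer(0)))
  do.call(rbind, rows)
}

#' Pairwise Mantel concordance of repeated measurement datasets
#'
#' Converts each matched dataset into a Euclidean distance matrix over
#' individuals and runs a one-sided Mantel test for every dataset pair of
#' the requested mode.  The resulting table of `R` (and permutation `p`)
#' values is the raw material for the hierarchical
#' measurer/species/method comparisons of [group_and_compare()].
#'
#' @param x a `shape_residuals` or standardized `distance_dataset` (or
#'   `list(labels, values)`) covering a complete crossed design.
#' @param mode `"repeatability"` or `"reproducibility"`.
#' @param n_perm permutations per Mantel test.
#' @param seed optional master seed; each pair gets its own sub-stream.
#' @param method optional method label (e.g. `"GMB"`) stored in the table.
#' @param mantel_mode passed to [mantel_test()] (`"auto"` enumerates
#'   exhaustively for very small populations).
#' @return a `concordance_table`: data frame with columns `method`, `mode`,
#'   `species`, `site`, `measurer_a`, `repeat_a`, `measurer_b`, `repeat_b`,
#'   `R`, `p`, `n`, `sig` (significance stars at 0.05/0.01).
#' @export
#' @examples
#' d <- design_spec(n_species = 1, n_populations = 2, n_individuals = 6,
#'                  seed = 5)
#' x <- generate_distances(d, effect_spec(), mode = "truss")
#' xs <- standardize(x, fit_allometry(x))
#' concordance(xs, "repeatability", n_perm = 99, seed = 1, method = "TRU")
concordance <- function(x, mode = c("repeatability", "reproducibility"),
                        n_perm = 999, seed = NULL, method = NA_character_,
                        mantel_mode = "auto") {
  mode <- match.arg(mode)
  sm <- specimen_matrices(x)
  pairs <- enumerate_pairs(sm, mode)
  n_pairs <- nrow(pairs)
  R <- numeric(n_pairs); p <- numeric(n_pairs); nn <- integer(n_pairs)
  dcache <- new.env(parent = emptyenv())
  dmat <- function(key) {
    if (is.null(dcache[[key]]))
      dcache[[key]] <- euclidean_distance_matrix(sm[[key]]$values)
    dcache[[key]]
  }
  for (i in seq_len(n_pairs)) {
    ka <- paste(pairs$species[i], pairs$site[i], pairs$measurer_a[i],
                pairs$repeat_a[i], sep = "|")
    kb <- paste(pairs$species[i], pairs$site[i], pairs$measurer_b[i],
                pairs$repeat_b[i], sep = "|")
    if (!identical(sm[[ka]]$individual_ids, sm[[kb]]$individual_ids))
      stop("individual sets differ between datasets ", ka, " and ", kb,
           call. = FALSE)
    mt <- mantel_test(dmat(ka), dmat(kb), n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else
                        stage_seed(seed, paste("mantel", ka, kb)),
                      mode = mantel_mode)
    R[i] <- mt$R; p[i] <- mt$p; nn[i] <- mt$n_specimens
  }
  out <- cbind(data.frame(method = method, mode = mode), pairs,
               data.frame(R = R, p = p, n = nn,
                          sig = ifelse(p < 0.01, "**",
                                       ifelse(p < 0.05, "*", ""))))
  structure(out, class = c("concordance_table", "data.frame"))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Concordance table (%s): %d pairwise Mantel tests\n",
              paste(unique(x$mode), collapse = "+"), nrow(x)))
  cat(sprintf("  R: mean %.3f, SD %.3f; significant at 0.05: %d/%d\n",
              mean(x$R), stats::sd(x$R), sum(x$p < 0.05), nrow(x)))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Compare Mantel R values between groups at a hierarchy level
#'
#' Arranges the R values of a concordance table (or several tables bound
#' together, e.g. across methods) into groups at the requested level and
#' compares them with Kruskal-Wallis tests.  For repeatability the levels
#' are measurer (groups of `n_repeat_pairs` values per site, compared
#' between measurers within method and species), species (compared within
#' method) and method; for reproducibility, species and method.  Pairwise
#' two-group Kruskal-Wallis tests at `alpha` feed a compact letter display:
#' groups sharing a letter are statistically indistinguishable.
#'
#' @param table a `concordance_table`, or an `rbind()` of several (one mode
#'   only).
#' @param level `"measurer"`, `"species"` or `"method"`.
#' @param alpha significance level for the pairwise tests.
#' @param p_adjust multiple-testing correction for the pairwise p-values
#'   (`"none"` by default; any method of [stats::p.adjust()]).
#' @return an object of class `"level_comparison"`: `summary` (group n,
#'   mean, SD, letter), `omnibus` (Kruskal-Wallis H, df, p per family) and
#'   `pairwise` (per-pair p-values) data frames.
#' @export
group_and_compare <- function(table, level = c("measurer", "species",
                                               "method"),
                              alpha = 0.05, p_adjust = "none") {
  level <- match.arg(level)
  table <- as.data.frame(table)
  mode <- unique(table$mode)
  if (length(mode) != 1)
    stop("mix of repeatability and reproducibility rows; compare one mode",
         call. = FALSE)
  if (mode == "reproducibility" && level == "measurer")
    stop("measurer level is undefined for reproducibility (each value spans two measurers)",
         call. = FALSE)
  fam_group <- switch(level,
    measurer = list(family = c("method", "species"), group = "measurer_a"),
    species  = list(family = "method",               group = "species"),
    method   = list(family = character(0),           group = "method"))
  fam <- if (length(fam_group$family))
    interaction(table[fam_group$family], drop = TRUE, sep = ":")
  else factor(rep("all", nrow(table)))
  grp <- table[[fam_group$group]]

  summaries <- list(); omnibus <- list(); pairwise <- list()
  for (f in levels(fam)) {
    sel <- fam == f
    vals <- split(table$R[sel], grp[sel])
    small <- names(vals)[lengths(vals) < 2]
    if (length(small)) {
      warning("excluding group(s) with < 2 values in family ", f, ": ",
              paste(small, collapse = ", "), call. = FALSE)
      vals <- vals[lengths(vals) >= 2]
    }
    if (length(vals) < 2)
      stop("fewer than 2 usable groups in family ", f, call. = FALSE)
    kw <- stats::kruskal.test(vals)
    omnibus[[f]] <- data.frame(family = f, H = unname(kw$statistic),
                               df = unname(kw$parameter), p = kw$p.value)
    gn <- names(vals)
    pw <- t(utils::combn(gn, 2))
    pp <- apply(pw, 1, function(g)
      stats::kruskal.test(list(vals[[g[1]]], vals[[g[2]]]))$p.value)
    padj <- stats::p.adjust(pp, method = p_adjust)
    pairwise[[f]] <- data.frame(family = f, group_a = pw[, 1],
                                group_b = pw[, 2], p = pp, p_adj = padj)
    letters <- .letter_display(gn, pw, padj < alpha,
                               means = vapply(vals, mean, numeric(1)))
    summaries[[f]] <- data.frame(
      family = f, group = gn, n = lengths(vals),
      mean = vapply(vals, mean, numeric(1)),
      sd = vapply(vals, stats::sd, numeric(1)),
      letter = letters[gn], row.names = NULL)
  }
  structure(list(summary = do.call(rbind, summaries),
                 omnibus = do.call(rbind, omnibus),
                 pairwise = do.call(rbind, pairwise),
                 level = level, mode = mode, alpha = alpha,
                 p_adjust = p_adjust),
            class = "level_comparison")
}

# compact letter display by insert-absorb over the non-significance graph:
# start from one set holding all groups; for each significant pair split any
# set containing both; absorb sets that became subsets of others.
.letter_display <- function(groups, pairs, significant, means) {
  sets <- list(groups)
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    if (!significant[i]) next
    a <- pairs[i, 1]; b <- pairs[i, 2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s)
        new_sets <- c(new_sets, list(setdiff(s, a), setdiff(s, b)))
      else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop sets strictly contained in another set, then duplicates
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) for (v in seq_along(new_sets)) {
      if (u != v && keep[v] &&
          length(new_sets[[u]]) < length(new_sets[[v]]) &&
          all(new_sets[[u]] %in% new_sets[[v]]))
        keep[u] <- FALSE
    }
    sets <- unique(new_sets[keep])
    sets <- sets[lengths(sets) > 0]
  }
  # order letter sets by the best (largest mean) group they contain
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' @export
print.level_comparison <- function(x, ...) {
  mode_lab <- paste0(toupper(substring(x$mode, 1, 1)), substring(x$mode, 2))
  cat(sprintf("%s at %s level (alpha = %.2f, %s-adjusted pairwise Kruskal-Wallis)\n",
              mode_lab, x$level, x$alpha, x$p_adjust))
  print(x$summary, row.names = FALSE, digits = 3)
  cat("Omnibus Kruskal-Wallis:\n")
  print(x$omnibus, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Boxplots of Mantel R values by group
#'
#' A compact version of the concordance figures: one box per group at the
#' chosen level, annotated with the letter display.
#'
#' @param x a `concordance_table`.
#' @param level hierarchy level passed to [group_and_compare()].
#' @param alpha significance level for the letters.
#' @param ... further arguments to [graphics::boxplot()].
#' @return the [group_and_compare()] result, invisibly.
#' @export
plot.concordance_table <- function(x, level = "method", alpha = 0.05, ...) {
  gc <- group_and_compare(x, level = level, alpha = alpha)
  fam_group <- switch(level,
    measurer = list(family = c("method", "species"), group = "measurer_a"),
    species  = list(family = "method", group = "species"),
    method   = list(family = character(0), group = "method"))
  key <- if (length(fam_group$family))
    paste(interaction(as.data.frame(x)[fam_group$family], drop = TRUE,
                      sep = ":"), x[[fam_group$group]], sep = "/")
  else x[[fam_group$group]]
  bp <- graphics::boxplot(split(x$R, key), ylab = "Mantel R",
                          main = sprintf("%s by %s", unique(x$mode), level),
                          las = 2, ...)
  lab <- gc$summary
  lab_key <- if (length(fam_group$family))
    paste(lab$family, lab$group, sep = "/") else lab$group
  graphics::text(match(lab_key, bp$names), lab$mean, lab$letter, pos = 3,
                 col = "red")
  invisible(gc)
}
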