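#' Fit the allometric size model for linear measurements
#'
#' Estimates, for every measurement variable, the power-law exponent `b`
#' relating it to standard length, as the slope of the ordinary
#' least-squares regression of `log10(M)` on `log10(SL)`.  Slopes are fitted
#' within each pooling group (default: per species per site) and combined as
#' a common within-group slope, weighting each group's slope by its residual
#' degrees of freedom.  `Ls`, the reference length of the adjustment, is the
#' arithmetic mean SL over the whole analysis set.  Records with zero
#' measurements are excluded from the slope fit of that variable (log is
#' undefined) with a warning.
#'
#' @param data a [distance_dataset()].
#' @param pooling character vector of label columns defining the regression
#'   groups.
#' @return an object of class `"allometric_model"`: per-variable exponent
#'   `b`, reference length `Ls`, the pooling used and per-variable fit
#'   standard errors.
#' @seealso [standardize()], [recheck_decorrelation()]
#' @references Elliott, N.G., Haskard, K. & Koslow, J.A. (1995) Morphometric
#'   analysis of orange roughy (Hoplostethus atlanticus) off the continental
#'   slope of southern Australia. Journal of Fish Biology 46, 202-220.
#' @export
#' @examples
#' x <- generate_distances(design_spec(n_species = 1, n_individuals = 10),
#'                         effect_spec(), mode = "truss")
#' mod <- fit_allometry(x)
#' round(coef(mod), 2)
fit_allometry <- function(data, pooling = c("species", "site")) {
  stopifnot(inherits(data, "distance_dataset"))
  stopifnot(all(pooling %in% .label_cols))
  vals <- dd_values(data)
  grp <- interaction(as.data.frame(data)[pooling], drop = TRUE, sep = ":")
  sl <- data$SL
  v <- ncol(vals)
  if (all(tapply(sl, grp, function(s) stats::var(s) < 1e-20)))
    stop("SL is constant within every pooling group; cannot estimate b",
         call. = FALSE)
  n_zero <- sum(vals == 0)
  if (n_zero > 0)
    warning(sprintf("%d zero measurement(s) excluded from slope fits", n_zero),
            call. = FALSE)

  b <- numeric(v); se <- numeric(v)
  lsl <- log10(sl)
  for (j in seq_len(v)) {
    num <- 0; den <- 0; df_tot <- 0
    for (g in levels(grp)) {
      i <- which(grp == g & vals[, j] > 0)
      if (length(i) < 3) next
      x <- lsl[i]; y <- log10(vals[i, j])
      sxx <- sum((x - mean(x))^2)
      if (sxx < 1e-20) next
      slope <- sum((x - mean(x)) * y) / sxx
      dfg <- length(i) - 2
      num <- num + dfg * slope
      den <- den + dfg
      df_tot <- df_tot + dfg
    }
    if (den == 0)
      stop(sprintf("cannot estimate b for variable %d: no usable group", j),
           call. = FALSE)
    b[j] <- num / den
    # pooled residual-based SE of the weighted common slope (approximate):
    # refit residual variance around the common slope, pooled over groups
    rss <- 0; sxx_tot <- 0
    for (g in levels(grp)) {
      i <- which(grp == g & vals[, j] > 0)
      if (length(i) < 3) next
      x <- lsl[i]; y <- log10(vals[i, j])
      sxx <- sum((x - mean(x))^2)
      if (sxx < 1e-20) next
      rss <- rss + sum((y - mean(y) - b[j] * (x - mean(x)))^2)
      sxx_tot <- sxx_tot + sxx
    }
    se[j] <- if (df_tot > 0 && sxx_tot > 0) sqrt(rss / df_tot / sxx_tot)
    else NA_real_
  }
  names(b) <- names(se) <- attr(data, "variable_names")
  structure(list(b = b, se = se, Ls = mean(sl), pooling = pooling,
                 n = nrow(data)),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("Allometric size model: %d variables, Ls = %.2f mm (n = %d)\n",
              length(x$b), x$Ls, x$n))
  cat(sprintf("  b: %.3f - %.3f (pooled by %s)\n", min(x$b), max(x$b),
              paste(x$pooling, collapse = ":")))
  invisible(x)
}

#' @export
coef.allometric_model <- function(object, ...) object$b

#' Allometric size standardization of linear measurements
#'
#' Adjusts every measurement to the size it would have at the reference
#' standard length: `M_adj = M * (Ls / L0)^b`, where `L0` is the specimen's
#' SL, `Ls` the overall mean SL of the analysis set and `b` the variable's
#' allometric exponent.  At `L0 = Ls`, or with `b = 0`, measurements are
#' unchanged.  `form = "printed"` applies the subtraction variant
#' `M * (Ls - L0)^b` instead; it is dimensionally inconsistent and not
#' idempotent, and is provided only for forensic comparison with sources
#' that print the formula that way.
#'
#' @param data a [distance_dataset()].
#' @param model an [fit_allometry()] model with a compatible variable set.
#' @param form `"ratio"` (default) or `"printed"`.
#' @return a [distance_dataset()] with adjusted measurements
#'   (`standardized` attribute set); labels and SL are preserved.
#' @export
standardize <- function(data, model, form = c("ratio", "printed")) {
  stopifnot(inherits(data, "distance_dataset"),
            inherits(model, "allometric_model"))
  form <- match.arg(form)
  vals <- dd_values(data)
  if (ncol(vals) != length(model$b))
    stop("model was fitted on a different variable set", call. = FALSE)
  if (any(data$SL <= 0)) stop("SL must be > 0", call. = FALSE)
  fac <- switch(form,
                ratio = outer(model$Ls / data$SL, model$b, `^`),
                printed = outer(model$Ls - data$SL, model$b, `^`))
  adj <- vals * fac
  if (form == "printed" && any(!is.finite(adj))) {
    # negative (Ls - L0) under a fractional exponent is undefined; this is
    # why the subtraction form cannot be a size adjustment
    warning(sprintf("printed form produced %d non-finite value(s); returning a plain data frame",
                    sum(!is.finite(adj))), call. = FALSE)
    return(cbind(as.data.frame(data)[c(.label_cols, "SL")],
                 as.data.frame(adj)))
  }
  distance_dataset(as.data.frame(data)[.label_cols], data$SL, adj,
                   variable_names = attr(data, "variable_names"),
                   mode = attr(data, "mode"), standardized = TRUE)
}

#' Check that standardized measurements are uncorrelated with size
#'
#' Pearson correlation of every (adjusted) measurement variable against
#' standard length, with the two-sided test p-value; a variable passes when
#' `p >= alpha`.  Variables with (numerically) zero variance have no defined
#' correlation and are reported as not applicable.
#'
#' @param data a [distance_dataset()], normally the output of
#'   [standardize()].
#' @param alpha significance level of the per-variable check.
#' @return an object of class `"decorrelation_check"`: a data frame with
#'   columns `variable`, `r`, `p`, `pass` (logical, `NA` where not
#'   applicable).
#' @export
recheck_decorrelation <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "distance_dataset"))
  if (nrow(data) < 3) stop("need at least 3 specimens", call. = FALSE)
  vals <- dd_values(data)
  out <- data.frame(variable = attr(data, "variable_names"),
                    r = NA_real_, p = NA_real_, pass = NA)
  for (j in seq_len(ncol(vals))) {
    if (stats::var(vals[, j]) < 1e-20 || stats::var(data$SL) < 1e-20) next
    ct <- stats::cor.test(vals[, j], data$SL)
    out$r[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
    out$pass[j] <- ct$p.value >= alpha
  }
  structure(out, alpha = alpha,
            class = c("decorrelation_check", "data.frame"))
}

#' @export
print.decorrelation_check <- function(x, ...) {
  n_ok <- sum(x$pass, na.rm = TRUE)
  n_na <- sum(is.na(x$pass))
  cat(sprintf("Size-decorrelation check (alpha = %.2f): %d/%d variables pass%s\n",
              attr(x, "alpha"), n_ok, nrow(x),
              if (n_na) sprintf(", %d not applicable", n_na) else ""))
  print(as.data.frame(x))
  invisible(x)
}
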