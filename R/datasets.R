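# Containers for labelled morphometric data.  Both are plain data frames
# (label columns first, then numeric columns) carrying attributes, so they
# print, subset and round-trip through CSV naturally.

.label_cols <- c("species", "site", "individual", "measurer", "repeat")

#' Labelled landmark dataset
#'
#' One row per digitized configuration: label columns `species`, `site`,
#' `individual`, `measurer`, `repeat`, followed by coordinate columns
#' `x1, y1, ..., xK, yK` in image units.
#'
#' @param labels data frame with the five label columns.
#' @param coords numeric matrix, one row per configuration, `2K` columns in
#'   x1,y1,... order.
#' @param landmark_names optional character vector of length `K`.
#' @param template optional template tag (`"body"` or `"scale"`).
#' @return object of class `"landmark_dataset"` (a data frame).
#' @export
landmark_dataset <- function(labels, coords, landmark_names = NULL,
                             template = NULL) {
  labels <- as.data.frame(labels)
  coords <- as.matrix(coords)
  if (!all(.label_cols %in% names(labels)))
    stop("labels must contain columns ", paste(.label_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(labels) != nrow(coords))
    stop("labels and coords disagree on the number of configurations",
         call. = FALSE)
  if (ncol(coords) %% 2 != 0)
    stop("coords must have an even number of columns (x,y pairs)",
         call. = FALSE)
  k <- ncol(coords) / 2
  if (anyNA(coords))
    stop("missing landmark coordinates are not supported", call. = FALSE)
  colnames(coords) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  if (is.null(landmark_names)) landmark_names <- paste0("lm", seq_len(k))
  if (length(landmark_names) != k)
    stop("landmark_names must have length K", call. = FALSE)
  out <- cbind(labels[.label_cols], as.data.frame(coords))
  dup <- duplicated(out[c("species", "site", "individual", "measurer",
                          "repeat")])
  if (any(dup))
    stop("duplicated (species, site, individual, measurer, repeat) records",
         call. = FALSE)
  structure(out, landmark_names = landmark_names, template = template,
            class = c("landmark_dataset", "data.frame"))
}

#' Labelled linear-distance dataset
#'
#' One row per measurement record: the five label columns, the standard
#' length `SL` (mm), and `V` measurement columns (mm).
#'
#' @param labels data frame with the five label columns.
#' @param SL numeric vector of standard lengths, mm, `> 0`.
#' @param variables numeric matrix of measurements, one column per variable.
#' @param variable_names optional character vector of length `V`.
#' @param mode optional tag (`"truss"` or `"caliper"`).
#' @param standardized logical, `TRUE` after allometric size adjustment.
#' @return object of class `"distance_dataset"` (a data frame).
#' @export
distance_dataset <- function(labels, SL, variables, variable_names = NULL,
                             mode = NULL, standardized = FALSE) {
  labels <- as.data.frame(labels)
  variables <- as.matrix(variables)
  if (!all(.label_cols %in% names(labels)))
    stop("labels must contain columns ", paste(.label_cols, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(SL)) || any(SL <= 0))
    stop("SL must be finite and > 0", call. = FALSE)
  if (anyNA(variables) || any(variables < 0))
    stop("measurements must be non-missing and >= 0", call. = FALSE)
  v <- ncol(variables)
  if (is.null(variable_names)) variable_names <- sprintf("var%02d", seq_len(v))
  if (length(variable_names) != v)
    stop("variable_names must have length V", call. = FALSE)
  colnames(variables) <- variable_names
  out <- cbind(labels[.label_cols], SL = as.numeric(SL),
               as.data.frame(variables))
  structure(out, variable_names = variable_names, mode = mode,
            standardized = standardized,
            class = c("distance_dataset", "data.frame"))
}

#' @export
print.landmark_dataset <- function(x, ...) {
  k <- length(attr(x, "landmark_names"))
  cat(sprintf("Landmark dataset: %d configurations x %d landmarks%s\n",
              nrow(x), k,
              if (!is.null(attr(x, "template")))
                paste0(" (", attr(x, "template"), " template)") else ""))
  cat(sprintf("  %d species, %d sites, %d measurers, %d repeats; %d stored values\n",
              length(unique(x$species)), length(unique(x$site)),
              length(unique(x$measurer)), length(unique(x[["repeat"]])),
              nrow(x) * k))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' @export
print.distance_dataset <- function(x, ...) {
  v <- length(attr(x, "variable_names"))
  cat(sprintf("Distance dataset: %d records x %d variables + SL%s%s\n",
              nrow(x), v,
              if (!is.null(attr(x, "mode")))
                paste0(" (", attr(x, "mode"), " mode)") else "",
              if (isTRUE(attr(x, "standardized")))
                ", size-standardized" else ""))
  cat(sprintf("  %d species, %d sites, %d measurers, %d repeats; %d measurement values\n",
              length(unique(x$species)), length(unique(x$site)),
              length(unique(x$measurer)), length(unique(x[["repeat"]])),
              nrow(x) * v))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

# coordinate block of a landmark dataset as a numeric matrix
lm_coords <- function(x) {
  stopifnot(inherits(x, "landmark_dataset"))
  as.matrix(x[, setdiff(names(x), .label_cols), drop = FALSE])
}

# measurement block of a distance dataset as a numeric matrix
dd_values <- function(x) {
  stopifnot(inherits(x, "distance_dataset"))
  as.matrix(x[, attr(x, "variable_names"), drop = FALSE])
}

# row subset that preserves class and attributes via the constructors
.subset_dataset <- function(x, idx) {
  df <- as.data.frame(x)[idx, , drop = FALSE]
  if (inherits(x, "landmark_dataset"))
    landmark_dataset(df[.label_cols],
                     as.matrix(df[setdiff(names(df), .label_cols)]),
                     landmark_names = attr(x, "landmark_names"),
                     template = attr(x, "template"))
  else if (inherits(x, "distance_dataset"))
    distance_dataset(df[.label_cols], df$SL,
                     as.matrix(df[attr(x, "variable_names")]),
                     variable_names = attr(x, "variable_names"),
                     mode = attr(x, "mode"),
                     standardized = attr(x, "standardized"))
  else stop("not a morphometric dataset", call. = FALSE)
}

#' Count the stored measurement values of a dataset
#'
#' For a landmark dataset, records times landmarks (each landmark counted as
#' one measured variable); for a distance dataset, records times measurement
#' variables (SL not counted).
#'
#' @param x a `landmark_dataset` or `distance_dataset`.
#' @return integer count.
#' @export
n_measurements <- function(x) {
  if (inherits(x, "landmark_dataset"))
    return(nrow(x) * length(attr(x, "landmark_names")))
  if (inherits(x, "distance_dataset"))
    return(nrow(x) * length(attr(x, "variable_names")))
  stop("not a morphometric dataset", call. = FALSE)
}
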