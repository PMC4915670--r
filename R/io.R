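# TPS and CSV readers/writers.  The TPS dialect follows the digitizing
# software convention: per-specimen records of an LM= line, LM coordinate
# lines, then key=value lines (ID=, IMAGE=, SCALE=, ...).  SCALE multiplies
# the coordinates on import; unknown keys are preserved on round-trip.
# Coordinates are taken with y increasing upward; CSV input is assumed
# already Cartesian.

#' Read a TPS landmark file
#'
#' Specimen labels are recovered from the `IMAGE=` field when it has the
#' form `species:site:individual:measurer:repeat` (the form written by
#' [write_landmarks_tps()]); otherwise the whole `IMAGE=` (or `ID=`) value
#' becomes the individual id and the remaining labels are set to `"NA"`
#' placeholders.
#'
#' @param path file path.
#' @return a [landmark_dataset()]; unrecognized per-record keys are kept in
#'   attribute `extra_keys`.
#' @export
read_landmarks_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE))
      stop(sprintf("line %d: expected LM= record start, got '%s'", i,
                   lines[i]), call. = FALSE)
    k <- suppressWarnings(as.integer(sub("^LM=", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1)
      stop(sprintf("line %d: invalid landmark count", i), call. = FALSE)
    start <- i; i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^[A-Za-z]+=", lines[i]))
        stop(sprintf("record starting at line %d: LM=%d but only %d coordinate line(s)",
                     start, k, j - 1L), call. = FALSE)
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (length(xy) != 2 || anyNA(xy))
        stop(sprintf("line %d: malformed coordinate line '%s'", i, lines[i]),
             call. = FALSE)
      coords[j, ] <- xy
      i <- i + 1L
    }
    keys <- character(0)
    while (i <= length(lines) && grepl("^[A-Za-z]+=", lines[i]) &&
           !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      keys <- c(keys, lines[i]); i <- i + 1L
    }
    kv <- sub("=.*$", "", keys)
    vv <- sub("^[A-Za-z]+=", "", keys)
    names(vv) <- toupper(kv)
    if ("SCALE" %in% names(vv))
      coords <- coords * as.numeric(vv[["SCALE"]])
    recs[[length(recs) + 1L]] <- list(coords = coords, keys = vv,
                                      raw_keys = keys)
  }
  if (!length(recs)) stop("empty TPS file", call. = FALSE)
  kk <- vapply(recs, function(r) nrow(r$coords), integer(1))
  if (length(unique(kk)) != 1)
    stop("mixed landmark counts across records: ",
         paste(unique(kk), collapse = ", "), call. = FALSE)

  labels <- do.call(rbind, lapply(recs, function(r) {
    img <- if ("IMAGE" %in% names(r$keys)) r$keys[["IMAGE"]] else
      if ("ID" %in% names(r$keys)) r$keys[["ID"]] else "unknown"
    parts <- strsplit(img, ":", fixed = TRUE)[[1]]
    if (length(parts) == 5)
      data.frame(species = parts[1], site = parts[2], individual = parts[3],
                 measurer = parts[4], "repeat" = as.integer(parts[5]),
                 check.names = FALSE)
    else
      data.frame(species = "NA", site = "NA", individual = img,
                 measurer = "NA", "repeat" = 1L, check.names = FALSE)
  }))
  coords <- do.call(rbind, lapply(recs, function(r) as.vector(t(r$coords))))
  out <- landmark_dataset(labels, coords)
  attr(out, "extra_keys") <- lapply(recs, function(r)
    r$raw_keys[!grepl("^(ID|IMAGE|SCALE)=", r$raw_keys, ignore.case = TRUE)])
  out
}

#' Write a landmark dataset as a TPS file
#'
#' @param x a [landmark_dataset()].
#' @param path file path.
#' @param scale optional `SCALE=` factor; coordinates are divided by it on
#'   write so a round-trip through [read_landmarks_tps()] is the identity.
#' @return `path`, invisibly.
#' @export
write_landmarks_tps <- function(x, path, scale = NULL) {
  stopifnot(inherits(x, "landmark_dataset"))
  coords <- lm_coords(x)
  k <- ncol(coords) / 2
  extra <- attr(x, "extra_keys")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    m <- matrix(coords[i, ], k, 2, byrow = TRUE)
    if (!is.null(scale)) m <- m / scale
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.10g %.10g", m[, 1], m[, 2]), con)
    writeLines(sprintf("IMAGE=%s:%s:%s:%s:%d", x$species[i], x$site[i],
                       x$individual[i], x$measurer[i], x[["repeat"]][i]),
               con)
    writeLines(sprintf("ID=%d", i), con)
    if (!is.null(scale)) writeLines(sprintf("SCALE=%.10g", scale), con)
    if (!is.null(extra) && length(extra) >= i && length(extra[[i]]))
      writeLines(extra[[i]], con)
  }
  invisible(path)
}

#' Read / write landmark datasets as CSV
#'
#' Layout: label columns `species,site,individual,measurer,repeat`, then
#' coordinate columns `x1,y1,...,xK,yK`.
#'
#' @param path file path.
#' @param x a [landmark_dataset()].
#' @return `read_landmark_csv()` a [landmark_dataset()];
#'   `write_landmark_csv()` the path, invisibly.
#' @export
read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  .check_csv_schema(df, path)
  cc <- setdiff(names(df), .label_cols)
  k <- length(cc) / 2
  want <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  if (!identical(cc, want))
    stop("coordinate columns must be x1,y1,...,xK,yK; got: ",
         paste(utils::head(cc, 6), collapse = ","), call. = FALSE)
  landmark_dataset(df[.label_cols], as.matrix(df[cc]))
}

#' @rdname read_landmark_csv
#' @export
write_landmark_csv <- function(x, path) {
  stopifnot(inherits(x, "landmark_dataset"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read / write distance datasets as CSV
#'
#' Layout: label columns, then `SL`, then the measurement variables.  When
#' writing a size-standardized dataset the variable columns get an `_adj`
#' suffix; the suffix is stripped again on read.
#'
#' @param path file path.
#' @param x a [distance_dataset()].
#' @return `read_distance_csv()` a [distance_dataset()];
#'   `write_distance_csv()` the path, invisibly.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  .check_csv_schema(df, path, need_sl = TRUE)
  vars <- setdiff(names(df), c(.label_cols, "SL"))
  standardized <- all(grepl("_adj$", vars)) && length(vars) > 0
  vn <- sub("_adj$", "", vars)
  distance_dataset(df[.label_cols], df$SL, as.matrix(df[vars]),
                   variable_names = vn, standardized = standardized)
}

#' @rdname read_distance_csv
#' @export
write_distance_csv <- function(x, path) {
  stopifnot(inherits(x, "distance_dataset"))
  df <- as.data.frame(x)
  if (isTRUE(attr(x, "standardized"))) {
    vn <- attr(x, "variable_names")
    names(df)[match(vn, names(df))] <- paste0(vn, "_adj")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.check_csv_schema <- function(df, path, need_sl = FALSE) {
  need <- c(.label_cols, if (need_sl) "SL")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  num_cols <- setdiff(names(df), .label_cols)
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))
      stop(sprintf("%s: non-numeric values in column '%s' (data line(s) %s)",
                   path, cc, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(df[[cc]]))
      stop(sprintf("%s: missing values in column '%s' (data line(s) %s)",
                   path, cc,
                   paste(utils::head(which(is.na(df[[cc]])), 5),
                         collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
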