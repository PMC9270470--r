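#' @title Readers and writers for the three interchange CSV schemas
#' @description Cavity records (site, cavity_id, stage, is_nest,
#'   orientation_deg), site metadata (site, latitude_deg, longitude_deg,
#'   optional bio1..bio19) and nest records (cluster_id, year, direction_deg,
#'   adults, eggs, hatchlings, fledglings). All readers validate schema and
#'   record-level invariants and normalise bearings into \[0, 360).
#' @name dataio
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

# Bearings may legitimately be recorded as 360.0; one modulo is applied.
# Anything outside [0, 720) before that modulo is treated as a recording error.
normalize_bearing <- function(x, what, rows = seq_along(x)) {
  bad <- which(is.na(x) | x < 0 | x >= 720)
  if (length(bad))
    stop(sprintf("%s: bearing out of [0, 720) at row(s) %s", what,
                 paste(rows[bad], collapse = ", ")), call. = FALSE)
  y <- x %% 360
  y[y >= 360] <- 0
  y
}

#' Read and validate a cavity-record CSV
#'
#' @param path path to a CSV with header columns \code{site, cavity_id,
#'   stage, is_nest, orientation_deg}; \code{stage} is "start" or "complete",
#'   \code{is_nest} is true/false. A nest must be a completed cavity.
#' @return validated data frame; orientations normalised into \[0, 360).
#' @export
read_cavities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("site", "cavity_id", "stage", "is_nest",
                        "orientation_deg"), "read_cavities")
  df$stage <- tolower(trimws(df$stage))
  bad <- which(!df$stage %in% c("start", "complete"))
  if (length(bad))
    stop("read_cavities: invalid stage at row(s) ",
         paste(bad, collapse = ", "), " (expected start/complete)", call. = FALSE)
  df$is_nest <- parse_logical(df$is_nest, "read_cavities")
  inconsistent <- which(df$is_nest & df$stage != "complete")
  if (length(inconsistent))
    stop("read_cavities: is_nest = true on a cavity start at row(s) ",
         paste(inconsistent, collapse = ", "),
         " (nests are chosen among completed cavities)", call. = FALSE)
  df$orientation_deg <- normalize_bearing(as.numeric(df$orientation_deg),
                                          "read_cavities")
  df
}

parse_logical <- function(x, what) {
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
  if (anyNA(out))
    stop(what, ": unparseable logical at row(s) ",
         paste(which(is.na(out)), collapse = ", "), call. = FALSE)
  out
}

#' Read and validate a site-metadata CSV
#'
#' @param path CSV with columns \code{site, latitude_deg, longitude_deg} and
#'   optionally the 19 bioclim columns \code{bio1..bio19}.
#' @return validated data frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("site", "latitude_deg", "longitude_deg"), "read_sites")
  if (any(abs(df$latitude_deg) > 90))
    stop("read_sites: latitude outside [-90, 90]", call. = FALSE)
  bio <- grep("^bio[0-9]+$", names(df), value = TRUE)
  if (length(bio) && !setequal(bio, paste0("bio", 1:19)))
    stop("read_sites: climate columns must be exactly bio1..bio19 (found ",
         length(bio), ")", call. = FALSE)
  if (anyDuplicated(df$site))
    stop("read_sites: duplicate site identifiers", call. = FALSE)
  df
}

#' Read and validate a nest-record CSV
#'
#' One record per cluster-year (first brood attempts only). Enforces
#' fledglings <= hatchlings <= eggs and adults >= 2 (a breeding pair).
#'
#' @param path CSV with columns \code{cluster_id, year, direction_deg,
#'   adults, eggs, hatchlings, fledglings}.
#' @return validated data frame.
#' @export
read_nests <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("cluster_id", "year", "direction_deg", "adults",
                        "eggs", "hatchlings", "fledglings"), "read_nests")
  key <- paste(df$cluster_id, df$year, sep = "\r")
  if (anyDuplicated(key))
    stop("read_nests: duplicate cluster-year pair(s): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  df$direction_deg <- normalize_bearing(as.numeric(df$direction_deg), "read_nests")
  for (col in c("adults", "eggs", "hatchlings", "fledglings")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      stop("read_nests: ", col, " must be non-negative integers", call. = FALSE)
  }
  if (any(df$adults < 2))
    stop("read_nests: adults < 2 (a breeding group needs at least a pair)",
         call. = FALSE)
  bad <- which(df$fledglings > df$hatchlings | df$hatchlings > df$eggs)
  if (length(bad))
    stop("read_nests: fledglings <= hatchlings <= eggs violated at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read cavity bearings from a supplementary raw-data export
#'
#' Loader for externally supplied raw cavity censuses whose column layout is
#' unknown in advance: a mapping list names which columns hold the site,
#' stage, nest flag and orientation, plus the stage labels used. The mapped
#' table is re-emitted in the package's cavity schema and passed through
#' \code{\link{read_cavities}}-level validation.
#'
#' @param path CSV path.
#' @param mapping named list with entries \code{site, stage, orientation}
#'   (column names), optional \code{is_nest} (column name) and
#'   \code{stage_labels} (named character vector mapping source labels to
#'   "start"/"complete").
#' @return validated cavity data frame.
#' @export
read_moesm1_cavities <- function(path,
                                 mapping = list(site = "site", stage = "stage",
                                                orientation = "orientation_deg",
                                                is_nest = "is_nest")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("site", "stage", "orientation"))
    if (!mapping[[f]] %in% names(df))
      stop("read_moesm1_cavities: mapped column '", mapping[[f]],
           "' not present", call. = FALSE)
  stage <- tolower(trimws(df[[mapping$stage]]))
  if (!is.null(mapping$stage_labels))
    stage <- unname(mapping$stage_labels[stage])
  is_nest <- if (!is.null(mapping$is_nest) && mapping$is_nest %in% names(df))
    parse_logical(df[[mapping$is_nest]], "read_moesm1_cavities") else FALSE
  out <- data.frame(site = df[[mapping$site]],
                    cavity_id = sprintf("m%06d", seq_len(nrow(df))),
                    stage = stage, is_nest = is_nest,
                    orientation_deg = as.numeric(df[[mapping$orientation]]),
                    stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(out, tmp, row.names = FALSE)
  read_cavities(tmp)
}

#' Write records to CSV (round-trip safe)
#' @param df data frame in one of the three schemas.
#' @param path output path.
#' @export
write_records <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load analysis configuration defaults
#'
#' Reads a YAML (if the \pkg{yaml} package is available) or JSON config file
#' holding defaults, and merges it over the package defaults
#' \code{iterations = 1000, conf = 0.95, seed = NULL}.
#'
#' @param path optional path to a .yaml/.yml/.json config file.
#' @return named list of settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(iterations = 1000L, conf = 0.95, seed = NULL)
  if (is.null(path)) return(defaults)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("load_config: yaml package not available for ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(defaults, cfg)
}

# One log line per pipeline event: subcommand, seed, input file digests.
log_line <- function(subcommand, seed = NULL, inputs = character(),
                     extra = NULL) {
  digests <- if (length(inputs))
    paste(sprintf("%s=%s", basename(inputs),
                  substr(unname(tools::md5sum(inputs)), 1, 8)), collapse = " ")
  else "none"
  msg <- sprintf("[cavorient] cmd=%s seed=%s inputs: %s%s", subcommand,
                 if (is.null(seed)) "NA" else seed, digests,
                 if (is.null(extra)) "" else paste0(" ", extra))
  message(msg)
  invisible(msg)
}
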