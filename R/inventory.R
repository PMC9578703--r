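#' Standardized tree-inventory data model
#'
#' An inventory is a `data.frame` with class `"inventory"`, one row per tree,
#' carrying the standardized columns used throughout the package. Columns
#' beyond the standard set are passed through untouched.
#'
#' @details Standard columns: `tree_id`, `scientific_name`, `common_name`,
#' `latitude`, `longitude`, `location_type` (`green_space`,
#' `built_environment`, `unknown`), `condition` (`excellent`, `good`, `fair`,
#' `poor`, `dead`, `dead_dying`, `unknown`), `native_status`
#' (`naturally_occurring`, `introduced`, `no_info`), `dbh_cm`, `height_m`.
#' Trees with unparseable species keep `scientific_name = "unknown"`; rows
#' with out-of-range coordinates are retained but flagged (attribute
#' `validation`) and skipped by spatial operations.
#'
#' @name inventory
NULL

CONDITION_LEVELS <- c("excellent", "good", "fair", "poor", "dead",
                      "dead_dying", "unknown")
LOCATION_LEVELS <- c("green_space", "built_environment", "unknown")
NATIVITY_LEVELS <- c("naturally_occurring", "introduced", "no_info")

STANDARD_COLUMNS <- c("city", "state", "tree_id", "scientific_name",
                      "common_name", "latitude", "longitude", "location_type",
                      "condition", "native_status", "dbh_cm", "height_m")

#' Build an inventory from a data frame
#'
#' Harmonizes enum columns, validates coordinates and measurements, and
#' attaches the per-row validation report.
#'
#' @param df data frame with at least `scientific_name` (or `common_name`) and
#'   coordinate columns.
#' @param city,state city name and two-letter state code; taken from `df`
#'   columns when present.
#' @param condition_map optional named vector or list mapping this city's raw
#'   condition labels/scores to the standard scale (see [condition_map()]).
#' @return An `inventory` data frame. Attribute `validation` is a data frame
#'   of per-row issues (row index, field, message); attribute `city`/`state`
#'   mirror the identifying columns.
#' @export
as_inventory <- function(df, city = NULL, state = NULL, condition_map = NULL) {
  stopifnot(is.data.frame(df))
  if (nrow(df) < 1L) stop("inventory must contain at least one tree")
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  if (is.null(city)) city <- if ("city" %in% names(df)) df$city[1L] else "unknown"
  if (is.null(state)) state <- if ("state" %in% names(df)) df$state[1L] else "NA"
  df$city <- as.character(city)
  df$state <- as.character(state)

  if (!("scientific_name" %in% names(df)) && !("common_name" %in% names(df)))
    stop("missing mandatory column: scientific_name (or common_name)")
  if (!("latitude" %in% names(df)) || !("longitude" %in% names(df)))
    stop("missing mandatory column: latitude/longitude")

  for (col in setdiff(STANDARD_COLUMNS, names(df)))
    df[[col]] <- switch(col,
      latitude = , longitude = , dbh_cm = , height_m = NA_real_,
      location_type = "unknown", condition = "unknown",
      native_status = "no_info", NA_character_)

  df$tree_id <- as.character(df$tree_id)
  df$common_name <- as.character(df$common_name)
  df$scientific_name <- trimws(as.character(df$scientific_name))
  df$scientific_name[is.na(df$scientific_name) | df$scientific_name == ""] <- "unknown"
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  df$dbh_cm <- as.numeric(df$dbh_cm)
  df$height_m <- as.numeric(df$height_m)

  df$condition <- harmonize_condition(df$condition, condition_map)
  df$location_type <- harmonize_enum(df$location_type, LOCATION_LEVELS)
  df$native_status <- harmonize_enum(df$native_status, NATIVITY_LEVELS,
                                     missing_level = "no_info")
  # genus-only records carry no nativity evidence
  df$native_status[genus_only(df$scientific_name)] <- "no_info"

  issues <- list()
  flag <- function(rows, field, msg) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(
        row = rows, field = field, message = msg, stringsAsFactors = FALSE)
  }
  bad_lat <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
  bad_lon <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
  flag(bad_lat, "latitude", "latitude outside [-90, 90]")
  flag(bad_lon, "longitude", "longitude outside [-180, 180]")
  flag(which(!is.na(df$dbh_cm) & df$dbh_cm <= 0), "dbh_cm", "non-positive dbh")
  flag(which(!is.na(df$height_m) & df$height_m <= 0), "height_m",
       "non-positive height")
  validation <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)

  df$coord_valid <- !is.na(df$latitude) & !is.na(df$longitude) &
    abs(df$latitude) <= 90 & abs(df$longitude) <= 180

  extra <- setdiff(names(df), c(STANDARD_COLUMNS, "coord_valid"))
  df <- df[, c(STANDARD_COLUMNS, "coord_valid", extra)]
  structure(df, class = c("inventory", "data.frame"),
            city = df$city[1L], state = df$state[1L], validation = validation)
}

harmonize_enum <- function(x, levels, missing_level = "unknown") {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ /-]+", "_", x)
  x[x == "dead/dying"] <- "dead_dying"
  x[is.na(x) | !(x %in% levels)] <- missing_level
  x
}

harmonize_condition <- function(x, condition_map = NULL) {
  x <- as.character(x)
  if (!is.null(condition_map)) {
    m <- unlist(condition_map)
    key <- tolower(trimws(x))
    hit <- match(key, tolower(trimws(names(m))))
    x <- ifelse(is.na(hit), x, unname(m[hit]))
  }
  harmonize_enum(x, CONDITION_LEVELS)
}

#' Define a city-specific condition mapping
#'
#' Source inventories score condition on incompatible scales (1-5 numbers,
#' three-point descriptive scales, ...); a condition map declares, per city,
#' how raw labels translate to the standard descriptive scale. Unmapped labels
#' fall through to `"unknown"`.
#'
#' @param ... named arguments, raw label = standard level, or a single named
#'   vector/list.
#' @return named character vector usable as `condition_map` in
#'   [read_inventory()]/[as_inventory()].
#' @examples
#' condition_map("5" = "excellent", "4" = "good", "3" = "fair",
#'               "2" = "poor", "1" = "dead")
#' @export
condition_map <- function(...) {
  m <- c(...)
  if (length(m) == 1L && is.list(..1)) m <- unlist(..1)
  m <- vapply(m, as.character, character(1))
  bad <- setdiff(unique(m), CONDITION_LEVELS)
  if (length(bad))
    stop("condition map targets outside the standard scale: ",
         paste(bad, collapse = ", "))
  m
}

#' Read a standardized city inventory CSV
#'
#' @param path CSV file; UTF-8, comma-separated, header row, `""` for missing.
#' @param condition_map optional [condition_map()] for this city's raw scale.
#' @return an [inventory] (see [as_inventory()] for validation semantics).
#' @export
read_inventory <- function(path, condition_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8", check.names = FALSE)
  as_inventory(df, condition_map = condition_map)
}

#' Write an inventory in the standardized CSV dialect
#'
#' UTF-8, comma-separated, header of standardized column names, `""` for
#' missing; re-reading reproduces the harmonized table.
#'
#' @param inv an [inventory].
#' @param path output file.
#' @export
write_inventory <- function(inv, path) {
  stopifnot(inherits(inv, "inventory"))
  out <- as.data.frame(inv)[, setdiff(names(inv), "coord_valid")]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

genus_only <- function(scientific_name) {
  nm <- trimws(scientific_name)
  nm != "unknown" & !grepl("\\s", nm)
}

#' @export
print.inventory <- function(x, ...) {
  cat(sprintf("<inventory> %s, %s: %d trees, %d species\n",
              attr(x, "city"), attr(x, "state"), nrow(x),
              length(unique(x$scientific_name[x$scientific_name != "unknown"]))))
  v <- attr(x, "validation")
  if (nrow(v)) cat(sprintf("  %d validation issue(s); see attr(, \"validation\")\n",
                           nrow(v)))
  print(utils::head(as.data.frame(x)[, c("tree_id", "scientific_name",
                                         "latitude", "longitude",
                                         "location_type", "condition",
                                         "native_status")]), ...)
  invisible(x)
}

#' Binary condition coding
#'
#' Collapses the descriptive condition scale to the binary used for condition
#' modelling: `excellent`/`good`/`fair` are 1, `poor`/`dead`/`dead_dying` are
#' 0, `unknown` is `NA`.
#'
#' @param condition character vector on the standard scale.
#' @return integer vector of 0/1/NA.
#' @export
condition_to_binary <- function(condition) {
  condition <- harmonize_enum(condition, CONDITION_LEVELS)
  out <- rep(NA_integer_, length(condition))
  out[condition %in% c("excellent", "good", "fair")] <- 1L
  out[condition %in% c("poor", "dead", "dead_dying")] <- 0L
  out
}

#' Species abundance table of an inventory
#'
#' Counts trees by scientific name, excluding unparseable (`"unknown"`)
#' records, and derives the frequency vector used by the diversity and
#' similarity machinery.
#'
#' @param inv an [inventory], or a character vector of species names.
#' @param filter optional predicate: a logical vector over rows, or a function
#'   taking the inventory data frame and returning one (e.g.
#'   `function(d) d$location_type == "green_space"`).
#' @return object of class `species_abundance`: list with `counts` (named,
#'   decreasing), `n` (total trees counted), `p` (frequencies, sum 1), and
#'   `n_unknown` (records excluded as unparseable).
#' @export
species_abundance <- function(inv, filter = NULL) {
  if (is.character(inv)) {
    species <- inv
    n_unknown <- sum(species == "unknown")
    species <- species[species != "unknown"]
  } else {
    stopifnot(is.data.frame(inv))
    keep <- rep(TRUE, nrow(inv))
    if (!is.null(filter)) {
      keep <- if (is.function(filter)) filter(as.data.frame(inv)) else filter
      stopifnot(is.logical(keep), length(keep) == nrow(inv))
      keep[is.na(keep)] <- FALSE
    }
    species <- inv$scientific_name[keep]
    n_unknown <- sum(species == "unknown")
    species <- species[species != "unknown"]
  }
  if (!length(species))
    return(structure(list(counts = integer(0), n = 0L, p = numeric(0),
                          n_unknown = n_unknown),
                     class = "species_abundance"))
  counts <- sort(table(species), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, n = sum(counts), p = counts / sum(counts),
                 n_unknown = n_unknown),
            class = "species_abundance")
}

#' @export
print.species_abundance <- function(x, ...) {
  cat(sprintf("<species_abundance> %d species, %d trees", length(x$counts), x$n))
  if (x$n_unknown) cat(sprintf(" (+%d unknown-species records excluded)", x$n_unknown))
  cat("\n")
  if (length(x$counts)) print(utils::head(x$counts, 10L))
  invisible(x)
}

is_empty_abundance <- function(x) inherits(x, "species_abundance") && x$n == 0L

as_species_abundance <- function(x) {
  if (inherits(x, "species_abundance")) return(x)
  if (is.data.frame(x)) return(species_abundance(x))
  if (is.numeric(x) && !is.null(names(x))) {
    x <- x[x > 0]
    counts <- sort(stats::setNames(as.integer(round(x)), names(x)),
                   decreasing = TRUE)
    return(structure(list(counts = counts, n = sum(counts),
                          p = counts / sum(counts), n_unknown = 0L),
                     class = "species_abundance"))
  }
  stop("cannot interpret as a species abundance")
}
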