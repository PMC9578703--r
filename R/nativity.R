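#' Read a state-by-taxon reference flora
#'
#' CSV with columns `state` (two-letter code) and `taxon` (scientific name):
#' the taxa naturally occurring in each state. Lookups are case-insensitive
#' on normalized binomials.
#'
#' @param path CSV file.
#' @param source_label provenance label stored with the table.
#' @return object of class `nativity_table`: `taxa` (named list,
#'   state -> character vector of normalized binomials), `source`.
#' @export
read_nativity_table <- function(path, source_label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("state", "taxon") %in% names(df)))
    stop("reference flora needs columns: state, taxon")
  nativity_table(split(df$taxon, toupper(df$state)), source_label)
}

#' Build a reference flora from a list
#'
#' @param taxa named list: state code -> character vector of taxa.
#' @param source_label provenance label.
#' @return a `nativity_table`.
#' @export
nativity_table <- function(taxa, source_label = "user") {
  stopifnot(is.list(taxa), !is.null(names(taxa)))
  taxa <- lapply(taxa, function(x) unique(normalize_binomial(x)))
  structure(list(taxa = stats::setNames(taxa, toupper(names(taxa))),
                 source = source_label),
            class = "nativity_table")
}

#' Normalize a scientific name to its binomial
#'
#' Lowercases, collapses whitespace, strips quoted cultivar epithets and
#' infraspecific qualifiers (`var.`, `ssp.`, `subsp.`, `f.`, `cv.`), and keeps
#' the first two tokens. Hybrid markers are retained, attached to the epithet
#' (`"Acer x freemanii"` stays distinct from `"Acer freemanii"`).
#'
#' @param x character vector of scientific names.
#' @return character vector of normalized binomials (or single genus tokens).
#' @export
normalize_binomial <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("['‘’\"].*$", "", x)               # cultivar in quotes
  x <- gsub("\\s+(var|ssp|subsp|f|cv)\\.?\\s.*$", "", x) # infraspecific rank
  x <- gsub("×", "x", x)                            # unicode multiplication sign
  x <- gsub("\\s+x\\s+", " x", x)                        # attach hybrid marker
  x <- gsub("\\s+", " ", trimws(x))
  vapply(strsplit(x, " "), function(t)
    paste(t[seq_len(min(2L, length(t)))], collapse = " "), character(1))
}

#' Nativity coding of species against a state's reference flora
#'
#' A binomial present in the state's list is `naturally_occurring`; a
#' resolvable binomial absent from it is `introduced`; genus-only records
#' carry no nativity evidence and are `no_info`.
#'
#' @param species character vector of scientific names.
#' @param state two-letter state code.
#' @param table a [nativity_table()].
#' @return character vector over
#'   `{naturally_occurring, introduced, no_info}`.
#' @export
assign_nativity <- function(species, state, table) {
  stopifnot(inherits(table, "nativity_table"))
  state <- toupper(state)
  if (!(state %in% names(table$taxa)))
    stop("state not in reference flora: ", state)
  ref <- table$taxa[[state]]
  norm <- normalize_binomial(species)
  out <- ifelse(norm %in% ref, "naturally_occurring", "introduced")
  out[!grepl(" ", norm) | norm == "unknown"] <- "no_info"
  out
}

#' Nativity summary of a city inventory
#'
#' Applies [assign_nativity()] to every tree and summarizes: counts by
#' status, percent naturally occurring, and for each introduced species
#' whether its genus contains at least one naturally occurring species in the
#' state's flora (native congener).
#'
#' @param inv an [inventory].
#' @param table a [nativity_table()]; when `NULL`, the inventory's existing
#'   `native_status` labels are summarized as-is.
#' @param denominator `"classified"` (default; excludes `no_info` trees from
#'   the percent-native denominator) or `"all"`.
#' @return object of class `nativity_summary`: `n_native`, `n_introduced`,
#'   `n_no_info`, `pct_native` (`NA` + flag when no tree is classified),
#'   `congeners` (data frame per introduced species), `labels`.
#' @export
nativity_summary <- function(inv, table = NULL,
                             denominator = c("classified", "all")) {
  denominator <- match.arg(denominator)
  state <- attr(inv, "state") %||% inv$state[1L]
  labels <- if (is.null(table)) inv$native_status
    else assign_nativity(inv$scientific_name, state, table)
  n_native <- sum(labels == "naturally_occurring")
  n_introduced <- sum(labels == "introduced")
  n_no_info <- sum(labels == "no_info")
  classified <- n_native + n_introduced
  pct_native <- if (denominator == "classified") {
    if (classified == 0L) NA_real_ else 100 * n_native / classified
  } else 100 * n_native / length(labels)
  congeners <- NULL
  if (!is.null(table)) {
    ref <- table$taxa[[toupper(state)]]
    native_genera <- unique(vapply(strsplit(ref[grepl(" ", ref)], " "),
                                   `[[`, character(1), 1L))
    intro_sp <- unique(normalize_binomial(
      inv$scientific_name[labels == "introduced"]))
    if (length(intro_sp)) {
      genus <- vapply(strsplit(intro_sp, " "), `[[`, character(1), 1L)
      congeners <- data.frame(species = intro_sp, genus = genus,
                              has_native_congener = genus %in% native_genera,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(n_native = n_native, n_introduced = n_introduced,
                 n_no_info = n_no_info, pct_native = pct_native,
                 pct_native_defined = !is.na(pct_native),
                 denominator = denominator, congeners = congeners,
                 labels = labels),
            class = "nativity_summary")
}

#' @export
print.nativity_summary <- function(x, ...) {
  cat(sprintf("<nativity_summary> %d native / %d introduced / %d no_info\n",
              x$n_native, x$n_introduced, x$n_no_info))
  if (x$pct_native_defined)
    cat(sprintf("  %.1f%% naturally occurring (%s denominator)\n",
                x$pct_native, x$denominator))
  else cat("  percent native undefined (no classified trees)\n")
  if (!is.null(x$congeners))
    cat(sprintf("  introduced species with a native congener: %d of %d\n",
                sum(x$congeners$has_native_congener), nrow(x$congeners)))
  invisible(x)
}
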