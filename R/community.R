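#' Construct a site-by-species community matrix
#'
#' The basic container consumed by every diversity statistic in the package:
#' a numeric matrix with sites in rows and species in columns, tagged with a
#' survey year and a measurement kind. Count matrices hold numbers of
#' individuals and must be integer-valued; biomass matrices hold mass in
#' grams and may be any non-negative real. The two kinds are kept as
#' separate objects and never mixed.
#'
#' @param x numeric matrix (or object coercible to one) with unique site row
#'   names and unique species column names; all entries must be finite and
#'   non-negative.
#' @param year integer survey-year label (may be `NA`).
#' @param kind `"count"` (individuals) or `"biomass"` (grams).
#' @return a `community_matrix`: the validated matrix with `year` and `kind`
#'   attributes.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' community_matrix(m, year = 2008)
#' @export
community_matrix <- function(x, year = NA_integer_, kind = c("count", "biomass")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community matrix needs site row names and species column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate site label: ", rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate species label: ", colnames(x)[duplicated(colnames(x))][1L])
  if (anyNA(x) || any(!is.finite(x)))
    stop("community matrix contains missing or non-finite values")
  if (any(x < 0))
    stop("community matrix contains negative abundances")
  if (kind == "count" && any(x != round(x)))
    stop("count matrices must contain integers only")
  structure(x, year = as.integer(year), kind = kind,
            class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix (%s): %d sites x %d species, year %s, total %g\n",
              attr(x, "kind"), nrow(x), ncol(x),
              ifelse(is.na(attr(x, "year")), "?", attr(x, "year")),
              sum(x)))
  print(unclass_cm(x), ...)
  invisible(x)
}

#' Survey year and measurement kind of a community matrix
#' @param cm a [community_matrix()].
#' @return integer year, or character kind.
#' @export
cm_year <- function(cm) attr(cm, "year")

#' @rdname cm_year
#' @export
cm_kind <- function(cm) attr(cm, "kind")

# strip class/attrs for plain matrix arithmetic
unclass_cm <- function(x) {
  y <- unclass(x)
  attr(y, "year") <- NULL
  attr(y, "kind") <- NULL
  y
}

# accept community_matrix or plain matrix throughout the package
as_abundance <- function(x) {
  if (inherits(x, "community_matrix")) return(unclass_cm(x))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Read a community matrix from delimited text
#'
#' Expects a header row of species labels and a first column of site labels;
#' the delimiter is comma or tab (sniffed from the first line unless given).
#' Blank cells are read as zero with a warning; non-numeric or negative cells
#' are hard errors naming the offending site and species.
#'
#' @param path file path.
#' @param year,kind passed to [community_matrix()].
#' @param sep field separator; `NULL` (default) sniffs `\t` vs `,`.
#' @return a [community_matrix()].
#' @export
read_community_matrix <- function(path, year = NA_integer_,
                                  kind = c("count", "biomass"), sep = NULL) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("no species columns found in ", path)
  sites <- df[[1L]]
  if (anyDuplicated(sites))
    stop("duplicate site label: ", sites[duplicated(sites)][1L])
  species <- colnames(df)[-1L]
  if (anyDuplicated(species))
    stop("duplicate species label: ", species[duplicated(species)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  blank <- is.na(vals) | !nzchar(trimws(vals))
  if (any(blank)) {
    warning(sum(blank), " blank cell(s) read as 0")
    vals[blank] <- "0"
  }
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at site '%s', species '%s'",
                 sites[idx[1L]], species[idx[2L]]))
  }
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at site '%s', species '%s'",
                 sites[idx[1L]], species[idx[2L]]))
  }
  dimnames(num) <- list(sites, species)
  community_matrix(num, year = year, kind = kind)
}

#' Write a community matrix to delimited text
#'
#' Inverse of [read_community_matrix()]; a write/read round trip reproduces
#' labels and entries exactly.
#'
#' @param cm a [community_matrix()].
#' @param path output file path.
#' @param sep field separator, default comma.
#' @export
write_community_matrix <- function(cm, path, sep = ",") {
  x <- as_abundance(cm)
  df <- data.frame(site = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reduce a community matrix to presence/absence
#'
#' Maps every positive entry to 1 and keeps labels; incidence input is the
#' natural domain of the Sorensen dissimilarity family. Idempotent.
#'
#' @param cm a [community_matrix()] or plain matrix.
#' @return a count-kind [community_matrix()] of 0/1 entries.
#' @export
presence_absence <- function(cm) {
  x <- as_abundance(cm)
  community_matrix((x > 0) + 0,
                   year = if (inherits(cm, "community_matrix")) cm_year(cm) else NA_integer_,
                   kind = "count")
}

#' Compare the species lists of two surveys
#'
#' Species are counted as present in a survey only when their total abundance
#' is positive, so a species retained in metadata but never observed is
#' treated as absent. Returns the lost, gained and shared sets going from
#' survey A to survey B.
#'
#' @param cm_a,cm_b community matrices sharing a species naming scheme.
#' @return a `species_turnover` list with `lost`, `gained`, `shared`.
#' @export
compare_species_lists <- function(cm_a, cm_b) {
  a <- as_abundance(cm_a)
  b <- as_abundance(cm_b)
  sp_a <- colnames(a)[colSums(a) > 0]
  sp_b <- colnames(b)[colSums(b) > 0]
  structure(list(lost = setdiff(sp_a, sp_b),
                 gained = setdiff(sp_b, sp_a),
                 shared = intersect(sp_a, sp_b)),
            class = "species_turnover")
}

#' @export
print.species_turnover <- function(x, ...) {
  cat(sprintf("species turnover: %d lost, %d gained, %d shared\n",
              length(x$lost), length(x$gained), length(x$shared)))
  if (length(x$lost)) cat("  lost:  ", paste(x$lost, collapse = ", "), "\n")
  if (length(x$gained)) cat("  gained:", paste(x$gained, collapse = ", "), "\n")
  invisible(x)
}

#' Read per-specimen survey records
#'
#' @param path CSV with columns `species`, `count`, `weight_g`, `length_cm`,
#'   `site`.
#' @return a data frame of the records.
#' @export
read_specimen_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "count", "weight_g", "length_cm", "site")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing specimen columns: ", paste(miss, collapse = ", "))
  if (any(df$count < 0) || any(df$weight_g < 0))
    stop("specimen counts and weights must be non-negative")
  df
}

#' Per-species specimen summary
#'
#' Aggregates specimen records into the per-species quantities that feed the
#' IRI and survey summaries: total individuals, total weight, mean body
#' length, and occurrence frequency (fraction of surveyed sites at which the
#' species was recorded).
#'
#' @param records data frame as returned by [read_specimen_records()].
#' @param n_sites total number of surveyed sites; defaults to the number of
#'   distinct sites appearing in `records`.
#' @return data frame with one row per species.
#' @export
specimen_table <- function(records, n_sites = length(unique(records$site))) {
  sp <- split(records, records$species)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(species = d$species[1L],
               total_count = sum(d$count),
               total_weight = sum(d$weight_g),
               mean_length = stats::weighted.mean(d$length_cm, d$count),
               occurrence_frequency = length(unique(d$site)) / n_sites)
  }))
  rownames(out) <- NULL
  out$pct_n <- 100 * out$total_count / sum(out$total_count)
  out$pct_w <- 100 * out$total_weight / sum(out$total_weight)
  out[order(-out$total_count), ]
}
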