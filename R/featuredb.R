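#' FeatureDatabase: embedded antemortem feature store
#'
#' Privacy-preserving database of computer-vision features: each entry holds
#' an individual identifier, the age at acquisition, and a serialized
#' [KeypointSet-class] — never pixel data (the descriptors do not allow
#' image reconstruction). One individual may own multiple entries. The store
#' is an in-memory table with single-file persistence
#' ([saveDatabase()] / [loadDatabase()]) and a schema version; entries are
#' indexed by age for radius queries.
#'
#' The object has reference semantics: [addEntry()] mutates the database in
#' place, as with any database handle.
#'
#' @slot store environment holding the entry table and counters.
#' @seealso [addEntry()], [queryByAge()], [asymmetricQuery()]
#' @export
setClass("FeatureDatabase", representation(store = "environment"))

.DB_SCHEMA_VERSION <- 1L

#' @rdname FeatureDatabase-class
#' @return An empty \code{FeatureDatabase}.
#' @examples
#' db <- FeatureDatabase()
#' dbSize(db)
#' @export
FeatureDatabase <- function() {
  store <- new.env(parent = emptyenv())
  store$schema_version <- .DB_SCHEMA_VERSION
  store$next_id <- 1L
  store$entry_id <- integer(0)
  store$individual_id <- character(0)
  store$age_years <- numeric(0)
  store$source_tag <- character(0)
  store$blobs <- list()
  new("FeatureDatabase", store = store)
}

#' @describeIn FeatureDatabase number of entries.
#' @param db a \code{FeatureDatabase}.
#' @export
setMethod("dbSize", "FeatureDatabase",
          function(db) length(db@store$entry_id))

setMethod("show", "FeatureDatabase", function(object) {
  s <- object@store
  cat(sprintf(
    "FeatureDatabase: %d entries, %d individuals (schema v%d)\n",
    length(s$entry_id), length(unique(s$individual_id)), s$schema_version))
  if (length(s$age_years))
    cat(sprintf("  age range: %.1f - %.1f years\n",
                min(s$age_years), max(s$age_years)))
})

#' Add an entry to a feature database
#'
#' @param db a [FeatureDatabase-class] (mutated in place).
#' @param individualId opaque individual identifier.
#' @param ageYears age at acquisition, in years (0-130).
#' @param features a [KeypointSet-class] or a raw blob produced by
#'   [serializeKeypointSet()] (validated on insert).
#' @param sourceTag optional provenance tag.
#' @return The new entry id (integer), invisibly.
#' @export
addEntry <- function(db, individualId, ageYears, features,
                     sourceTag = NA_character_) {
  stopifnot(is(db, "FeatureDatabase"))
  if (is.na(ageYears) || ageYears < 0 || ageYears > 130)
    stop("ageYears must lie in [0, 130]")
  blob <- if (is.raw(features)) features else {
    stopifnot(is(features, "KeypointSet"))
    serializeKeypointSet(features)
  }
  # integrity check: blob must parse back
  deserializeKeypointSet(blob)
  s <- db@store
  id <- s$next_id
  s$next_id <- id + 1L
  s$entry_id <- c(s$entry_id, id)
  s$individual_id <- c(s$individual_id, as.character(individualId))
  s$age_years <- c(s$age_years, as.numeric(ageYears))
  s$source_tag <- c(s$source_tag, as.character(sourceTag))
  s$blobs[[as.character(id)]] <- blob
  invisible(id)
}

#' Entry table of a feature database
#'
#' @param db a [FeatureDatabase-class].
#' @return data.frame with columns \code{entry_id}, \code{individual_id},
#'   \code{age_years}, \code{source_tag} in insertion order.
#' @export
dbEntries <- function(db) {
  stopifnot(is(db, "FeatureDatabase"))
  s <- db@store
  data.frame(entry_id = s$entry_id, individual_id = s$individual_id,
             age_years = s$age_years, source_tag = s$source_tag,
             stringsAsFactors = FALSE)
}

#' Fetch one database entry
#'
#' @param db a [FeatureDatabase-class].
#' @param entryId entry identifier.
#' @param withFeatures deserialize the stored [KeypointSet-class]?
#' @return A list with elements \code{entry_id}, \code{individual_id},
#'   \code{age_years}, \code{source_tag}, and (if requested)
#'   \code{features}.
#' @export
getEntry <- function(db, entryId, withFeatures = TRUE) {
  stopifnot(is(db, "FeatureDatabase"))
  s <- db@store
  i <- match(entryId, s$entry_id)
  if (is.na(i)) stop("no entry with id ", entryId)
  out <- list(entry_id = s$entry_id[i], individual_id = s$individual_id[i],
              age_years = s$age_years[i], source_tag = s$source_tag[i])
  if (withFeatures)
    out$features <- deserializeKeypointSet(s$blobs[[as.character(entryId)]])
  out
}

#' Stored features of one entry
#'
#' @inheritParams getEntry
#' @return The entry's [KeypointSet-class].
#' @export
entryFeatures <- function(db, entryId) {
  getEntry(db, entryId, withFeatures = TRUE)$features
}

# shared ordering rule: ascending |age - center|, ties by ascending entry id
.orderedCandidates <- function(db, center, lower, upper) {
  tab <- dbEntries(db)
  keep <- tab$age_years >= lower & tab$age_years <= upper
  tab <- tab[keep, , drop = FALSE]
  if (is.na(center)) {
    tab <- tab[order(tab$entry_id), , drop = FALSE]
    tab$delta_age <- NA_real_
  } else {
    tab$delta_age <- abs(tab$age_years - center)
    tab <- tab[order(tab$delta_age, tab$entry_id), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Query database entries within an age radius
#'
#' Returns exactly the entries with \code{|age - center| <= radius},
#' ordered ascending by absolute age difference (ties broken by ascending
#' entry id) — the order in which an age-gated search visits candidates.
#'
#' @param db a [FeatureDatabase-class].
#' @param centerYears search center (estimated age), in years.
#' @param radiusYears non-negative radius; \code{Inf} disables filtering.
#' @return data.frame of matching entries with a \code{delta_age} column.
#' @examples
#' db <- FeatureDatabase()
#' @export
queryByAge <- function(db, centerYears, radiusYears) {
  if (radiusYears < 0) stop("radius must be >= 0")
  .orderedCandidates(db, centerYears,
                     centerYears - radiusYears, centerYears + radiusYears)
}

#' Age query with different younger/older radii
#'
#' Like [queryByAge()] but with an asymmetric window
#' \code{[center - radiusYounger, center + radiusOlder]}; used to widen the
#' search toward younger ages for elderly subjects, whose ages tend to be
#' underestimated.
#'
#' @inheritParams queryByAge
#' @param radiusYounger,radiusOlder non-negative radii in years.
#' @return data.frame of matching entries with a \code{delta_age} column.
#' @export
asymmetricQuery <- function(db, centerYears, radiusYounger, radiusOlder) {
  if (radiusYounger < 0 || radiusOlder < 0) stop("radii must be >= 0")
  .orderedCandidates(db, centerYears,
                     centerYears - radiusYounger, centerYears + radiusOlder)
}

#' Persist or restore a feature database
#'
#' Single-file persistence of the whole store (entries, blobs, counters,
#' schema version).
#'
#' @param db a [FeatureDatabase-class].
#' @param path file path.
#' @return \code{saveDatabase}: \code{path}, invisibly;
#'   \code{loadDatabase}: the restored [FeatureDatabase-class].
#' @export
saveDatabase <- function(db, path) {
  stopifnot(is(db, "FeatureDatabase"))
  s <- db@store
  payload <- list(schema_version = s$schema_version, next_id = s$next_id,
                  entry_id = s$entry_id, individual_id = s$individual_id,
                  age_years = s$age_years, source_tag = s$source_tag,
                  blobs = s$blobs)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveDatabase
#' @export
loadDatabase <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema_version, .DB_SCHEMA_VERSION))
    stop("unsupported database schema version")
  db <- FeatureDatabase()
  s <- db@store
  for (nm in c("next_id", "entry_id", "individual_id", "age_years",
               "source_tag", "blobs"))
    assign(nm, payload[[nm]], envir = s)
  db
}
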