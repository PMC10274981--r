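#' Read a delimited table with comma/tab auto-detection
#'
#' @param path File path; the delimiter is chosen by counting tabs vs commas
#'   in the header row. A header row is required.
#' @return data.frame with \code{stringsAsFactors = FALSE}.
#' @keywords internal
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))))
    "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Load and validate a regional SUVR table
#'
#' Accepts long format (columns \code{subject_id}, \code{region_id},
#' \code{suvr} plus either \code{scan_date} or \code{visit_index} [+
#' \code{years_from_first_scan}]) or wide format (\code{subject_id}, a visit
#' column, and one column per region). The format is auto-detected from the
#' header. Region names are normalized (FreeSurfer-style and plain dialects
#' both accepted), visits are re-indexed chronologically per subject starting
#' at 0, and \code{years_from_first_scan} is computed from scan dates when
#' dates are given (365.25-day years).
#'
#' @param path CSV/TSV path.
#' @param registry A \code{region_registry}.
#' @return A validated long-format data.frame of class \code{suvr_table} with
#'   columns \code{subject_id}, \code{visit_index},
#'   \code{years_from_first_scan}, \code{region_id}, \code{suvr}.
#' @export
load_suvr_table <- function(path, registry = region_registry()) {
  raw <- read_delim_auto(path)
  names(raw)[names(raw) == "subject"] <- "subject_id"
  if (!"subject_id" %in% names(raw))
    stop("missing mandatory column: subject_id")
  long <- if ("suvr" %in% names(raw) &&
              any(c("region_id", "region") %in% names(raw))) {
    names(raw)[names(raw) %in% c("region")] <- "region_id"
    raw
  } else {
    wide_to_long_suvr(raw, registry)
  }
  as_suvr_table(long, registry)
}

wide_to_long_suvr <- function(wide, registry) {
  meta_cols <- intersect(names(wide),
                         c("subject_id", "scan_date", "visit_index",
                           "years_from_first_scan", "visit"))
  region_cols <- setdiff(names(wide), meta_cols)
  norm <- normalize_region_id(region_cols)
  unknown <- region_cols[!norm %in% registry$region_id]
  if (length(unknown))
    message("ignoring ", length(unknown), " unknown region column(s): ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
  keep <- region_cols[norm %in% registry$region_id]
  if (!length(keep)) stop("no recognizable region columns in wide table")
  long <- do.call(rbind, lapply(seq_along(keep), function(i) {
    out <- wide[meta_cols]
    out$region_id <- normalize_region_id(keep[i])
    out$suvr <- wide[[keep[i]]]
    out
  }))
  rownames(long) <- NULL
  long
}

#' Validate a long-format SUVR table
#'
#' @param long data.frame with at least \code{subject_id}, \code{region_id},
#'   \code{suvr} and visit information (\code{scan_date} or
#'   \code{visit_index}/\code{years_from_first_scan}).
#' @param registry A \code{region_registry}.
#' @return A \code{suvr_table} (see \code{\link{load_suvr_table}}).
#' @export
as_suvr_table <- function(long, registry = region_registry()) {
  need <- c("subject_id", "region_id", "suvr")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  long$region_id <- normalize_region_id(long$region_id)
  bad <- setdiff(unique(long$region_id), registry$region_id)
  if (length(bad))
    stop("unknown region_id(s) not in registry: ",
         paste(utils::head(bad, 8L), collapse = ", "),
         if (length(bad) > 8L) ", ...")

  # visit timeline: prefer explicit years, else derive from scan dates
  if ("scan_date" %in% names(long) &&
      !"years_from_first_scan" %in% names(long)) {
    d <- as.Date(long$scan_date)
    if (anyNA(d)) stop("unparseable scan_date values")
    first <- tapply(as.numeric(d), long$subject_id, min)
    long$years_from_first_scan <-
      (as.numeric(d) - first[as.character(long$subject_id)]) / 365.25
  }
  if (!"years_from_first_scan" %in% names(long)) {
    if (!"visit_index" %in% names(long))
      stop("missing mandatory column(s): scan_date or visit_index/",
           "years_from_first_scan")
    long$years_from_first_scan <- as.numeric(long$visit_index)
  }
  # chronological re-indexing per subject
  long$visit_index <- stats::ave(long$years_from_first_scan, long$subject_id,
    FUN = function(y) match(y, sort(unique(y))) - 1L)

  bad_suvr <- which(!is.finite(long$suvr) | long$suvr <= 0)
  if (length(bad_suvr))
    stop("non-positive or non-finite SUVR at row(s): ",
         paste(utils::head(bad_suvr, 8L), collapse = ", "),
         " (subject ", long$subject_id[bad_suvr[1L]],
         ", region ", long$region_id[bad_suvr[1L]], ")")

  dup <- duplicated(long[c("subject_id", "visit_index", "region_id")])
  if (any(dup))
    stop("duplicate (subject, visit, region) keys, first at row ",
         which(dup)[1L])

  # full 70-region coverage per (subject, visit)
  sv <- paste(long$subject_id, long$visit_index, sep = "\r")
  cnt <- table(sv)
  off <- names(cnt)[cnt != nrow(registry)]
  if (length(off)) {
    first_off <- strsplit(off[1L], "\r", fixed = TRUE)[[1L]]
    have <- long$region_id[sv == off[1L]]
    missing_r <- setdiff(registry$region_id, have)
    extra_r <- have[duplicated(have)]
    stop("subject ", first_off[1L], " visit ", first_off[2L], " has ",
         cnt[off[1L]], " regions (expected ", nrow(registry), "); missing: ",
         paste(utils::head(missing_r, 5L), collapse = ", "),
         if (length(extra_r)) paste0("; duplicated: ",
                                     paste(utils::head(extra_r, 5L),
                                           collapse = ", ")))
  }

  out <- long[order(long$subject_id, long$visit_index,
                    match(long$region_id, registry$region_id)),
              c("subject_id", "visit_index", "years_from_first_scan",
                "region_id", "suvr")]
  rownames(out) <- NULL
  class(out) <- c("suvr_table", "data.frame")
  out
}

#' Load subject metadata
#'
#' @param path CSV/TSV with columns \code{subject_id}, \code{diagnosis}
#'   (CU/MCI/AD), \code{abeta_positive} (logical or 0/1), \code{centiloid},
#'   \code{age}, \code{sex} (F/M), \code{education}.
#' @return data.frame, one row per subject.
#' @export
load_metadata <- function(path) {
  md <- read_delim_auto(path)
  need <- c("subject_id", "diagnosis", "abeta_positive", "centiloid",
            "age", "sex", "education")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$subject_id))
    stop("duplicate subject_id in metadata")
  if (!all(md$diagnosis %in% c("CU", "MCI", "AD")))
    stop("diagnosis must be CU, MCI or AD")
  md$abeta_positive <- as.logical(md$abeta_positive)
  if (any(!is.finite(md$centiloid))) stop("non-finite centiloid values")
  md
}

#' Load longitudinal cognitive composite scores
#'
#' @param path CSV/TSV with columns \code{subject_id},
#'   \code{years_from_first_cognitive_visit}, \code{composite} (memory /
#'   executive / language / visuospatial), \code{score}.
#' @return data.frame of visit-level composite scores.
#' @export
load_cognition <- function(path) {
  cg <- read_delim_auto(path)
  need <- c("subject_id", "years_from_first_cognitive_visit", "composite",
            "score")
  miss <- setdiff(need, names(cg))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  ok <- c("memory", "executive", "language", "visuospatial")
  if (!all(cg$composite %in% ok))
    stop("composite must be one of ", paste(ok, collapse = ", "))
  dup <- duplicated(cg[c("subject_id", "years_from_first_cognitive_visit",
                         "composite")])
  if (any(dup)) stop("duplicate (subject, visit, composite) rows")
  cg
}

#' Serialize a threshold set to JSON
#'
#' Cutoffs and mixture parameters are written at full double precision so
#' that binarization after a round trip is bit-identical.
#'
#' @param thresholds A \code{threshold_set} from
#'   \code{\link{fit_all_thresholds}}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  payload <- list(
    region_cutoffs = as.list(thresholds$region_cutoffs),
    stage_cutoffs  = as.list(thresholds$stage_cutoffs),
    region_fits    = lapply(thresholds$region_fits, unclass),
    stage_fits     = lapply(thresholds$stage_fits, unclass),
    flags          = thresholds$flags)
  # I(17) = 17 significant digits, enough to reproduce any double exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a threshold set from JSON
#'
#' @param path JSON written by \code{\link{write_thresholds}}.
#' @param registry A \code{region_registry}; the file must cover every
#'   registry region.
#' @return A \code{threshold_set}.
#' @export
load_thresholds <- function(path, registry = region_registry()) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  rc <- unlist(payload$region_cutoffs)
  miss <- setdiff(registry$region_id, names(rc))
  if (length(miss))
    stop("threshold file does not cover region(s): ",
         paste(miss, collapse = ", "))
  fits <- lapply(payload$region_fits, function(f) {
    f <- lapply(f, function(v) if (is.list(v)) unlist(v) else v)
    class(f) <- "mixture_fit"
    f
  })
  sfits <- lapply(payload$stage_fits, function(f) {
    f <- lapply(f, function(v) if (is.list(v)) unlist(v) else v)
    class(f) <- "mixture_fit"
    f
  })
  out <- list(region_cutoffs = rc[registry$region_id],
              stage_cutoffs  = unlist(payload$stage_cutoffs),
              region_fits    = fits,
              stage_fits     = sfits,
              flags          = lapply(payload$flags, unlist))
  class(out) <- "threshold_set"
  out
}
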