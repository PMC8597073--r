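#' Read a symptom checklist file
#'
#' Parses the checklist dialect used throughout the package: one row per
#' checklist item with columns `symptom`, `observed` (`yes`, `no` or `na`)
#' and `orientation` (`good` or `bad`). The orientation column qualifies
#' the row *as observed* — e.g. an absent elevated central venous pressure
#' is recorded as `observed = no, orientation = good`, contributing one
#' Good-indicative signal — so every row with `observed` of `yes` or `no`
#' contributes exactly one oriented signal, and `na` rows (not assessed)
#' contribute nothing.
#'
#' @param path Path to a checklist file.
#' @param dialect `"csv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return A [checklist_assessment()] with a `parse_report` attribute
#'   (counts of good/bad/skipped rows).
#' @export
read_checklist <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("checklist file not found: ", path, call. = FALSE)
  raw <- if (dialect == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  names(raw) <- tolower(names(raw))
  needed <- c("symptom", "observed", "orientation")
  if (!all(needed %in% names(raw))) {
    stop("checklist must have columns symptom, observed, orientation ",
         "(case-insensitive); found: ", paste(names(raw), collapse = ", "),
         call. = FALSE)
  }
  raw$observed <- tolower(trimws(as.character(raw$observed)))
  raw$orientation <- tolower(trimws(as.character(raw$orientation)))
  bad_obs <- !raw$observed %in% c("yes", "no", "na")
  if (any(bad_obs)) {
    stop("row ", which(bad_obs)[1], " ('", raw$symptom[which(bad_obs)[1]],
         "'): observed must be yes, no or na", call. = FALSE)
  }
  keep <- raw$observed != "na"
  kept <- raw[keep, , drop = FALSE]
  bad_or <- !kept$orientation %in% c("good", "bad")
  if (any(bad_or)) {
    stop("row ", which(keep)[which(bad_or)[1]], " ('",
         kept$symptom[which(bad_or)[1]],
         "'): unknown orientation token '", kept$orientation[which(bad_or)[1]],
         "'", call. = FALSE)
  }
  cl <- checklist_assessment(kept$symptom, kept$orientation)
  if (cl$n == 0) warning("checklist contains no signals", call. = FALSE)
  attr(cl, "parse_report") <- c(good = cl$n - cl$b, bad = cl$b,
                                skipped = sum(!keep))
  cl
}

#' Write a checklist assessment to file
#'
#' Serializes to the same dialect accepted by [read_checklist()]; the
#' round trip reproduces the assessment exactly.
#'
#' @param checklist A [checklist_assessment()].
#' @param path Destination path; extension picks csv or json.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  stopifnot(inherits(checklist, "fontan_checklist"))
  out <- data.frame(symptom = checklist$entries$symptom,
                    observed = "yes",
                    orientation = checklist$entries$orientation,
                    stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read model parameters from a JSON configuration
#'
#' Expects a JSON object with fields `mu`, `theta`, `r`, `delta`, `LT`,
#' `LNT` (years and per-year rates). An optional `review_interval_years`
#' field rescales a per-interval comorbidity count to the canonical
#' per-year rate at load time.
#'
#' @param path Path to the JSON file.
#' @return A validated [fontan_params()] object.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path)
  needed <- c("mu", "theta", "r", "delta", "LT", "LNT")
  if (!all(needed %in% names(cfg))) {
    stop("config must define ", paste(needed, collapse = ", "), call. = FALSE)
  }
  mu <- cfg$mu
  if (!is.null(cfg$review_interval_years)) {
    if (cfg$review_interval_years <= 0) {
      stop("review_interval_years must be > 0", call. = FALSE)
    }
    mu <- mu / cfg$review_interval_years
  }
  fontan_params(mu = mu, theta = cfg$theta, r = cfg$r, delta = cfg$delta,
                LT = cfg$LT, LNT = cfg$LNT)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the parameters, the seed,
#' the package and R versions, and any extra fields supplied.
#'
#' @param path Destination path.
#' @param params A [fontan_params()] object.
#' @param seed Integer seed used for the run (or `NA`).
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, seed = NA, extra = list()) {
  params <- as_fontan_params(params)
  manifest <- c(list(
    package = "fontanlist",
    package_version = as.character(utils::packageVersion("fontanlist")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    params = params[c("mu", "theta", "r", "delta", "LT", "LNT", "p0")]
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
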