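#' Construct a ratings table
#'
#' Human causal-judgment ratings: one row per participant, one integer
#' rating in `[0, 10]` per rated unit (agreement with "the candidate won the
#' presidency because he won [unit]"), plus per-participant metadata
#' (`voted_for`, `party_id`, `believes_legitimate`). Every participant rates
#' every unit; structural missingness is rejected.
#'
#' @param ratings Integer matrix, participants x units, entries in
#'   `[0, 10]`; row and column names required.
#' @param meta Data frame with a `participant` column matching the rating
#'   rows, plus metadata columns.
#' @return Object of class `ratings_table`: list with `ratings`, `meta`,
#'   `units`, `participants`.
#' @export
ratings_table <- function(ratings, meta) {
  ratings <- as.matrix(ratings)
  if (is.null(rownames(ratings)) || is.null(colnames(ratings))) {
    stop("`ratings` needs participant row names and unit column names",
      call. = FALSE
    )
  }
  bad <- which(is.na(ratings) | ratings != round(ratings) |
    ratings < 0 | ratings > 10, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1L, function(ix) {
      paste0(rownames(ratings)[ix[1]], "/", colnames(ratings)[ix[2]])
    })
    stop(
      "ratings must be integers in [0, 10]; offending cells: ",
      paste(cells, collapse = ", "),
      if (nrow(bad) > 10) sprintf(" (and %d more)", nrow(bad) - 10) else "",
      call. = FALSE
    )
  }
  storage.mode(ratings) <- "integer"
  stopifnot(is.data.frame(meta), "participant" %in% names(meta))
  if (!identical(sort(meta$participant), sort(rownames(ratings)))) {
    stop("`meta$participant` must match the rating rows", call. = FALSE)
  }
  meta <- meta[match(rownames(ratings), meta$participant), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(
      ratings = ratings, meta = meta,
      units = colnames(ratings), participants = rownames(ratings)
    ),
    class = "ratings_table"
  )
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(
    "<ratings_table> ", nrow(x$ratings), " participants x ",
    ncol(x$ratings), " units\n",
    sep = ""
  )
  invisible(x)
}

#' Read a forecast simulation file into a world ensemble
#'
#' Supported dialects:
#' \describe{
#'   \item{`vote_share_csv`}{Wide CSV, one row per simulation, one column
#'     per unit, entries the focal candidate's two-party vote share in
#'     `[0, 1]`. A unit is won iff its share is strictly greater than
#'     `win_threshold` (default 0.5; a share of exactly 0.5 is not a win —
#'     ties are measure-zero in real files but the rule must be pinned for
#'     reproducibility).}
#'   \item{`binary_csv`}{Same layout with 0/1 entries, taken as-is.}
#'   \item{`simmed_maps_json`}{JSON object with a `states` array of unit
#'     names and a `maps` array of simulations, each either an array of
#'     vote shares aligned with `states` or an object keyed by unit name.}
#' }
#' `dialect = "auto"` picks `simmed_maps_json` for `.json` files, then
#' sniffs the first data row of a CSV: any entry outside `{0, 1}` means
#' vote shares.
#'
#' District-level units (names like `ME-1`) can be passed through as units
#' of their own or collapsed into their parent state with
#' `collapse_districts = TRUE` (shares averaged across a state's rows;
#' electoral votes must then be supplied at state level in `map`).
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"vote_share_csv"`, `"binary_csv"`,
#'   `"simmed_maps_json"`.
#' @param map Optional [electoral_map] giving electoral votes; by default
#'   units are matched against [us_electoral_map_2020()] and the map is
#'   subset/ordered accordingly (all file units must be known).
#' @param win_threshold Share above which a unit counts as won (strict
#'   inequality).
#' @param collapse_districts Collapse `XX-n` district columns into `XX`.
#' @return A [world_ensemble] with uniform weights. The number of rows read
#'   is reported with a message.
#' @export
read_simulations <- function(path,
                             dialect = c(
                               "auto", "vote_share_csv",
                               "binary_csv", "simmed_maps_json"
                             ),
                             map = NULL, win_threshold = 0.5,
                             collapse_districts = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      "simmed_maps_json"
    } else {
      "csv_sniff"
    }
  }

  if (dialect == "simmed_maps_json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(doc$states) || is.null(doc$maps)) {
      stop("simmed_maps_json needs `states` and `maps` fields", call. = FALSE)
    }
    units <- as.character(doc$states)
    maps <- doc$maps
    if (is.matrix(maps)) {
      shares <- maps
      colnames(shares) <- units
    } else if (is.data.frame(maps)) {
      missing <- setdiff(units, names(maps))
      if (length(missing)) {
        stop("simulation entries missing units: ",
          paste(missing, collapse = ", "),
          call. = FALSE
        )
      }
      shares <- as.matrix(maps[, units, drop = FALSE])
    } else {
      stop("unrecognized `maps` layout", call. = FALSE)
    }
    is_share <- TRUE
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    shares <- as.matrix(df)
    if (!is.numeric(shares)) {
      stop("simulation CSV must be numeric", call. = FALSE)
    }
    is_share <- switch(dialect,
      vote_share_csv = TRUE,
      binary_csv = FALSE,
      csv_sniff = !all(shares[1L, ] %in% c(0, 1))
    )
  }

  if (anyNA(shares)) {
    stop("simulation file contains missing values", call. = FALSE)
  }

  if (collapse_districts) {
    state_of <- sub("-.*$", "", colnames(shares))
    if (!identical(state_of, colnames(shares))) {
      shares <- vapply(
        unique(state_of),
        function(s) rowMeans(shares[, state_of == s, drop = FALSE]),
        numeric(nrow(shares))
      )
    }
  }

  if (is_share) {
    if (any(shares < 0 | shares > 1)) {
      stop("vote shares must lie in [0, 1]", call. = FALSE)
    }
    outcomes <- (shares > win_threshold) + 0L
  } else {
    check_binary(shares, "outcomes")
    outcomes <- shares
  }

  if (is.null(map)) {
    full <- us_electoral_map_2020()
    unknown <- setdiff(colnames(outcomes), full$units)
    if (length(unknown)) {
      stop(
        "unknown units (supply `map`): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    keep <- full$units %in% colnames(outcomes)
    # partial coverage: fall back to a majority threshold over the units
    # actually present (the 270 rule only makes sense on the full map)
    map <- electoral_map(full$units[keep], full$votes[keep],
      threshold = if (all(keep)) full$threshold else NULL
    )
  }
  ens <- world_ensemble(map, outcomes)
  message(sprintf("read %d simulations x %d units", nrow(outcomes),
                  ncol(outcomes)))
  ens
}

#' Read a ratings CSV
#'
#' Wide CSV with a `participant` column, optional metadata columns
#' (`voted_for`, `party_id`, `believes_legitimate`, `group`), and one column
#' of integer 0-10 ratings per unit. Validation failures list the offending
#' cells.
#'
#' @param path File path.
#' @return A [ratings_table].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"participant" %in% names(df)) {
    stop("ratings CSV needs a `participant` column", call. = FALSE)
  }
  meta_cols <- intersect(
    c("participant", "voted_for", "party_id", "believes_legitimate", "group"),
    names(df)
  )
  unit_cols <- setdiff(names(df), meta_cols)
  if (length(unit_cols) == 0L) {
    stop("ratings CSV has no unit columns", call. = FALSE)
  }
  ratings <- as.matrix(df[, unit_cols, drop = FALSE])
  rownames(ratings) <- df$participant
  meta <- df[, meta_cols, drop = FALSE]
  if ("believes_legitimate" %in% names(meta)) {
    meta$believes_legitimate <- as.logical(meta$believes_legitimate)
  }
  ratings_table(ratings, meta)
}

#' Write a table to CSV
#'
#' Writes causal score tables, results data frames, or ratings tables with a
#' stable column order and `NA` cells as empty strings, so that a write/read
#' round trip is the identity on valid tables.
#'
#' @param table A data frame (e.g. a [score_all()] result) or a
#'   [ratings_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (inherits(table, "ratings_table")) {
    df <- cbind(table$meta, as.data.frame(table$ratings))
  } else {
    df <- as.data.frame(table)
  }
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("refusing to write an empty table", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a causal score table CSV
#'
#' Counterpart of [write_table()] for unit-by-measure score tables: a `unit`
#' column plus numeric measure columns, empty cells read as `NA`.
#'
#' @param path File path.
#' @return Data frame with `unit` first.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    na.strings = ""
  )
  if (!"unit" %in% names(df)) {
    stop("score table needs a `unit` column", call. = FALSE)
  }
  df
}
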