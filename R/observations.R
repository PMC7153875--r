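#' @title Focal observation records
#' @description
#' Focal-sampling observation data: one row per timed behavioural event
#' recorded while one individual (the focal) was watched. Behaviours fall
#' into three interaction classes: grooming and feeding proximity are timed
#' (duration in seconds), aggression and supplant/avoidance are point events
#' counted once per record and merged downstream into a single agonism
#' class.
#' @name focal-records
NULL

.behaviors <- c("groom", "feed_proximity", "aggression", "supplant_avoid")
.duration_behaviors <- c("groom", "feed_proximity")

# interaction class -> contributing behaviour codes
.type_behaviors <- list(
  grooming  = "groom",
  proximity = "feed_proximity",
  agonism   = c("aggression", "supplant_avoid")
)

#' Read focal observation records from CSV
#'
#' The file must have the header
#' `session_id,period_id,focal_id,behavior,actor_id,recipient_id,duration_s`.
#' Every row is validated: the behaviour code must be one of `groom`,
#' `feed_proximity`, `aggression`, `supplant_avoid`; actor and recipient
#' must differ; the focal must be one of the two; timed behaviours need a
#' positive duration while point events must have zero (or empty) duration.
#'
#' @param path path to the CSV file.
#' @return a `data.frame` of validated records, row order preserved, with
#'   class `focal_records`.
#' @export
read_focal_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("session_id", "period_id", "focal_id", "behavior",
            "actor_id", "recipient_id", "duration_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$duration_s[df$duration_s == ""] <- "0"
  dur <- suppressWarnings(as.numeric(df$duration_s))
  if (anyNA(dur))
    stop("non-numeric duration_s at row ", which(is.na(dur))[1], call. = FALSE)
  df$duration_s <- dur
  validate_focal_records(df)
}

#' Validate a data frame of focal records
#'
#' @param df data frame with the focal-record columns.
#' @return the validated data frame, classed `focal_records`.
#' @export
validate_focal_records <- function(df) {
  bad <- function(rows, why) {
    if (length(rows))
      stop("invalid record at row ", rows[1], ": ", why, call. = FALSE)
  }
  bad(which(!df$behavior %in% .behaviors),
      paste0("unknown behavior code '",
             df$behavior[which(!df$behavior %in% .behaviors)[1]], "'"))
  bad(which(df$actor_id == df$recipient_id), "actor equals recipient")
  bad(which(df$focal_id != df$actor_id & df$focal_id != df$recipient_id),
      "focal is neither actor nor recipient")
  bad(which(df$duration_s < 0), "negative duration")
  timed <- df$behavior %in% .duration_behaviors
  bad(which(timed & df$duration_s <= 0),
      "timed behavior requires a positive duration")
  bad(which(!timed & df$duration_s != 0),
      "point-event behavior must have zero duration")
  class(df) <- c("focal_records", "data.frame")
  df
}

#' Write focal records to CSV
#'
#' @param records a `focal_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_focal_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a sampling-effort table from CSV
#'
#' Expected header: `period_id,individual_id,focal_hours`. Hours must be
#' positive.
#'
#' @param path path to the CSV file.
#' @param period_id optional period to select; required when the file
#'   contains several periods.
#' @return named numeric vector of focal hours, names = individual ids.
#' @export
read_sampling_effort <- function(path, period_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("period_id", "individual_id", "focal_hours")
  if (!all(need %in% names(df)))
    stop("effort file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(period_id)) df <- df[df$period_id == period_id, ]
  if (nrow(df) == 0) stop("no effort rows", call. = FALSE)
  if (length(unique(df$period_id)) > 1)
    stop("effort file spans several periods; pass period_id", call. = FALSE)
  sampling_effort(stats::setNames(df$focal_hours, df$individual_id))
}

#' Construct a sampling-effort vector
#'
#' @param hours named numeric vector: focal observation hours per
#'   individual; all positive.
#' @return the validated named vector.
#' @export
sampling_effort <- function(hours) {
  if (is.null(names(hours)) || any(names(hours) == ""))
    stop("effort hours must be named by individual", call. = FALSE)
  if (anyDuplicated(names(hours)))
    stop("duplicated individual in effort table", call. = FALSE)
  if (any(!is.finite(hours)) || any(hours <= 0))
    stop("all focal hours must be positive", call. = FALSE)
  hours
}

#' Sum dyadic interaction totals from focal records
#'
#' Collapses direction: every occurrence between the two members of a dyad
#' is summed regardless of who acted. Grooming and proximity totals are
#' summed durations in seconds; agonism totals are episode counts
#' (aggression records plus supplant/avoidance records).
#'
#' @param records a `focal_records` data frame.
#' @param type one of `"grooming"`, `"proximity"`, `"agonism"`.
#' @param universe character vector of individual ids defining the analysis
#'   universe; every individual referenced by a record of this type must be
#'   in it.
#' @return a `dyadic_totals` object: list with `type`, `universe`, and the
#'   symmetric totals `matrix` (zero diagonal).
#' @export
dyadic_totals <- function(records, type = c("grooming", "proximity", "agonism"),
                          universe) {
  type <- match.arg(type)
  stopifnot(is.character(universe), length(universe) >= 2)
  if (anyDuplicated(universe)) stop("duplicated id in universe", call. = FALSE)
  rec <- records[records$behavior %in% .type_behaviors[[type]], , drop = FALSE]
  ids <- unique(c(rec$actor_id, rec$recipient_id))
  unknown <- setdiff(ids, universe)
  if (length(unknown))
    stop("record references individual(s) outside the universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(universe)
  m <- matrix(0, n, n, dimnames = list(universe, universe))
  if (nrow(rec)) {
    val <- if (type == "agonism") rep(1, nrow(rec)) else rec$duration_s
    for (k in seq_len(nrow(rec))) {
      a <- rec$actor_id[k]; b <- rec$recipient_id[k]
      m[a, b] <- m[a, b] + val[k]
      m[b, a] <- m[b, a] + val[k]
    }
  }
  structure(list(type = type, universe = universe, matrix = m),
            class = "dyadic_totals")
}

#' Construct dyadic totals directly from a matrix
#'
#' For workflows starting from precomputed symmetric dyadic matrices rather
#' than raw focal records.
#'
#' @param m symmetric nonnegative matrix with individual ids as dimnames and
#'   zero diagonal.
#' @param type interaction class label.
#' @return a `dyadic_totals` object.
#' @export
as_dyadic_totals <- function(m, type = "grooming") {
  check_dyadic_matrix(m, "dyadic totals")
  structure(list(type = type, universe = rownames(m), matrix = m),
            class = "dyadic_totals")
}

#' @export
print.dyadic_totals <- function(x, ...) {
  cov <- dyad_coverage(x)
  cat(sprintf("Dyadic totals (%s): %d individuals, %d/%d dyads observed (%.1f%%), grand total %g\n",
              x$type, length(x$universe), cov$n_observed, cov$n_possible,
              cov$percent, upper_sum(x$matrix)))
  invisible(x)
}

#' Dyad coverage: how many possible dyads were observed interacting
#'
#' @param totals a `dyadic_totals` object (an index matrix also works).
#' @return list with `n_possible` (= n(n-1)/2), `n_observed` (dyads with a
#'   positive total) and `percent` (half-up rounded to one decimal).
#' @export
dyad_coverage <- function(totals) {
  m <- totals$matrix %||% totals$weights
  n <- nrow(m)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  possible <- n * (n - 1) / 2
  observed <- sum(m[upper.tri(m)] > 0)
  list(n_possible = possible, n_observed = observed,
       percent = round_half_up(100 * observed / possible, 1))
}

#' Per-hour dyadic interaction rates
#'
#' The rate of a dyad is its total divided by the dyad's observation time,
#' taken as the sum of both members' focal hours (a dyad is on view whenever
#' either member is the focal). Mean and SD are computed across ALL possible
#' dyads, zeros included.
#'
#' @param totals a `dyadic_totals` object.
#' @param effort named numeric vector of focal hours per individual (see
#'   [sampling_effort()]); must cover the whole universe.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a `rate_summary` list: `per_dyad` (named vector, "A-B" keys),
#'   `mean`, `sd`, `n_possible`, `n_observed`, `percent_observed`.
#' @export
dyadic_rates <- function(totals, effort, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  u <- totals$universe
  missing_ids <- setdiff(u, names(effort))
  if (length(missing_ids))
    stop("no effort hours for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  pairs <- dyad_pairs(u)
  tot <- totals$matrix[cbind(pairs[, 1], pairs[, 2])]
  hours <- effort[pairs[, 1]] + effort[pairs[, 2]]
  rate <- tot / hours
  names(rate) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  sdv <- if (length(rate) > 1) {
    v <- stats::sd(rate)
    if (sd_type == "population") v * sqrt((length(rate) - 1) / length(rate)) else v
  } else 0
  cov <- dyad_coverage(totals)
  structure(list(per_dyad = rate, mean = mean(rate), sd = sdv,
                 n_possible = cov$n_possible, n_observed = cov$n_observed,
                 percent_observed = cov$percent, type = totals$type),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%s: %d/%d dyads observed (%.1f%%); mean rate %.2f +/- %.2f per dyadic hour\n",
              x$type, x$n_observed, x$n_possible, x$percent_observed,
              round_half_up(x$mean, 2), round_half_up(x$sd, 2)))
  invisible(x)
}

#' Per-behaviour record counts
#'
#' Reports how many records (and, for timed behaviours, how many seconds)
#' each behaviour code contributed, keeping the agonism subtypes
#' distinguishable even though they are merged into one agonism layer.
#'
#' @param records a `focal_records` data frame.
#' @return data frame with columns `behavior`, `n_records`, `total_duration_s`.
#' @export
behavior_summary <- function(records) {
  out <- do.call(rbind, lapply(.behaviors, function(b) {
    r <- records[records$behavior == b, , drop = FALSE]
    data.frame(behavior = b, n_records = nrow(r),
               total_duration_s = sum(r$duration_s))
  }))
  rownames(out) <- NULL
  out
}
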