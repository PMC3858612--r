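.agonisticCodes <- c("chase", "charge", "bite", "grab",
                     "flee", "displace", "jump_away")
.affiliativeCodes <- c("groom")

#' Classify a social interaction event
#'
#' Agonistic codes (aggressive: chase, charge, bite, grab; submissive:
#' flee, displace, jump_away) dominate any distance. Otherwise grooming or
#' sitting within 1 m is affiliative; sitting within 5 m without agonistic
#' or affiliative behavior is neutral; beyond 5 m there is no event
#' (`"none"`). Events lacking both codes and a distance are rejected.
#'
#' @param codes character vector of behavior codes (may be empty).
#' @param distance inter-individual distance in m, or `NA`.
#' @return one of `"agonistic"`, `"affiliative"`, `"neutral"`, `"none"`.
#' @export
classifyInteraction <- function(codes = character(0), distance = NA) {
  codes <- codes[nzchar(codes)]
  known <- c(.agonisticCodes, .affiliativeCodes)
  if (length(codes) && !all(codes %in% known))
    stop("unknown behavior code(s): ",
         paste(setdiff(codes, known), collapse = ", "))
  if (any(codes %in% .agonisticCodes)) return("agonistic")
  if (any(codes %in% .affiliativeCodes)) return("affiliative")
  if (is.na(distance)) {
    if (!length(codes))
      stop("event has neither behavior codes nor a distance")
    return("none")
  }
  if (distance <= 1) "affiliative"
  else if (distance <= 5) "neutral"
  else "none"
}

#' Read an interaction-event CSV
#'
#' Columns: `timestamp, actor_id, receiver_id, codes, distance_m` (codes
#' semicolon-separated, possibly empty; distance may be empty). Each row
#' is classified with [classifyInteraction()]; rows classified `"none"`
#' are dropped.
#'
#' @param file CSV path.
#' @return data.frame with `t, actor_id, receiver_id, klass, distance_m`.
#' @export
readInteractions <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("timestamp", "actor_id", "receiver_id", "codes", "distance_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  klass <- vapply(seq_len(nrow(df)), function(i) {
    codes <- strsplit(as.character(df$codes[i]), ";")[[1]]
    classifyInteraction(codes, suppressWarnings(
      as.numeric(df$distance_m[i])))
  }, "")
  out <- data.frame(t = df$timestamp, actor_id = df$actor_id,
                    receiver_id = df$receiver_id, klass = klass,
                    distance_m = suppressWarnings(
                      as.numeric(df$distance_m)),
                    stringsAsFactors = FALSE)
  out[out$klass != "none", , drop = FALSE]
}

#' Read a sleeping-site CSV
#'
#' Columns: `date, individual_id, tree_id`; one record per individual per
#' date (duplicates are an error).
#'
#' @param file CSV path.
#' @return validated data.frame.
#' @export
readSleepRecords <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("date", "individual_id", "tree_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("date", "individual_id")]))
    stop("more than one sleeping record for an individual on one date")
  df
}

#' Per-dyad social interaction rates (events per hour in sight)
#'
#' Counts events of each class per dyad and divides by the dyad's hours of
#' simultaneous in-sight observation, rounding to 2 decimals for report
#' parity; then summarizes per-class unweighted means and SDs across
#' dyads with [summarizeRates()].
#'
#' @param events data.frame as returned by [readInteractions()] (a dyad is
#'   the unordered `{actor_id, receiver_id}` pair).
#' @param hoursInSight named numeric vector: hours per dyad, names
#'   `"idA.idB"` with the two ids sorted (or a data.frame with columns
#'   `dyad, hours`).
#' @return list with `rates` (per-dyad data.frame: dyad, neutral,
#'   agonistic, affiliative, total, hours) and `summary` (per-class mean
#'   and sd rows).
#' @export
interactionRates <- function(events, hoursInSight) {
  if (is.data.frame(hoursInSight))
    hoursInSight <- stats::setNames(hoursInSight$hours, hoursInSight$dyad)
  if (any(hoursInSight <= 0)) stop("hours in sight must be positive")
  if (is.null(events$klass)) {      # raw event log: classify on the fly
    events$klass <- vapply(seq_len(nrow(events)), function(i) {
      codes <- strsplit(as.character(events$codes[i]), ";")[[1]]
      classifyInteraction(codes, suppressWarnings(
        as.numeric(events$distance_m[i])))
    }, "")
    events <- events[events$klass != "none", , drop = FALSE]
  }
  dyad <- apply(cbind(events$actor_id, events$receiver_id), 1,
                function(r) paste(sort(r), collapse = "."))
  rows <- lapply(names(hoursInSight), function(dn) {
    h <- hoursInSight[[dn]]
    k <- dyad == dn
    counts <- vapply(c("neutral", "agonistic", "affiliative"),
                     function(cl) sum(k & events$klass == cl), 0)
    rates <- round(counts / h, 2)
    data.frame(dyad = dn, neutral = rates[1], agonistic = rates[2],
               affiliative = rates[3], total = round(sum(counts) / h, 2),
               hours = h, stringsAsFactors = FALSE, row.names = NULL)
  })
  rates <- do.call(rbind, rows)
  list(rates = rates, summary = summarizeRates(rates))
}

#' Summarize a per-dyad rate table
#'
#' Unweighted per-class means and SDs across dyads, rounded to 2 decimals.
#'
#' @param rates data.frame with columns `neutral, agonistic, affiliative,
#'   total` (one row per dyad).
#' @return data.frame with rows `mean` and `sd`.
#' @export
summarizeRates <- function(rates) {
  cols <- c("neutral", "agonistic", "affiliative", "total")
  m <- vapply(cols, function(cl) mean(rates[[cl]]), 0)
  s <- vapply(cols, function(cl) stats::sd(rates[[cl]]), 0)
  out <- rbind(mean = round(m, 2), sd = round(s, 2))
  as.data.frame(out)
}

#' Sleeping-association tally per dyad
#'
#' For each male-female dyad: the number of dates with a record for either
#' partner (`observation_days`), trees used by exactly one partner
#' (`exclusive_m`, `exclusive_f`), trees used by both partners on any
#' dates (`shared_trees`), and dates on which both slept in the same tree
#' (`simultaneous_days`).
#'
#' @param records sleeping data.frame (see [readSleepRecords()]).
#' @param dyads data.frame with columns `male_id, female_id`.
#' @return data.frame, one row per dyad.
#' @export
sleepingTally <- function(records, dyads) {
  rows <- lapply(seq_len(nrow(dyads)), function(i) {
    m <- records[records$individual_id == dyads$male_id[i], ]
    f <- records[records$individual_id == dyads$female_id[i], ]
    treesM <- unique(m$tree_id); treesF <- unique(f$tree_id)
    shared <- intersect(treesM, treesF)
    joint <- merge(m, f, by = "date")
    data.frame(
      male_id = dyads$male_id[i], female_id = dyads$female_id[i],
      observation_days = length(union(m$date, f$date)),
      exclusive_m = length(setdiff(treesM, treesF)),
      exclusive_f = length(setdiff(treesF, treesM)),
      shared_trees = length(shared),
      simultaneous_days = sum(joint$tree_id.x == joint$tree_id.y),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
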