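#' Write range polygons to GeoJSON
#'
#' One Feature per [RangePolygon-class], geometry `Polygon` (planar local
#' coordinates, not longitude/latitude), properties `individual_id`,
#' `isopleth`, `area_ha`, `bandwidth_m`. Full numeric precision.
#'
#' @param polys list of [RangePolygon-class] objects.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeRangesGeoJSON <- function(polys, file) {
  feats <- lapply(polys, function(p) {
    rings <- lapply(p@rings, function(r) {
      r <- rbind(r, r[1, ])                      # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    props <- list(individual_id = p@id, isopleth = p@level,
                  area_ha = p@areaHa)
    if (is.finite(p@h)) props$bandwidth_m <- p@h   # NA (MCP) -> omitted
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = rings),
         properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), file,
    auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read range polygons from GeoJSON
#'
#' Inverse of [writeRangesGeoJSON()]; closing vertices are stripped so a
#' round trip reproduces the rings (and hence areas) exactly.
#'
#' @param file GeoJSON path.
#' @return list of [RangePolygon-class] objects.
#' @export
readRangesGeoJSON <- function(file) {
  gj <- jsonlite::read_json(file)
  lapply(gj$features, function(ft) {
    rings <- lapply(ft$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt)
        c(pt[[1]], pt[[2]])))
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
        m <- m[-nrow(m), , drop = FALSE]
      m
    })
    pr <- ft$properties
    h <- pr$bandwidth_m
    new("RangePolygon", id = pr$individual_id, level = pr$isopleth,
        rings = rings, areaHa = pr$area_ha,
        h = if (is.numeric(h)) h else NA_real_)
  })
}

# infer male-female pairs by maximum female-side range overlap
.inferPairs <- function(ranges, sexes) {
  males <- names(sexes)[sexes == "M"]
  females <- names(sexes)[sexes == "F"]
  rows <- lapply(females, function(f) {
    ov <- vapply(males, function(m)
      percentOverlap(ranges[[f]], ranges[[m]])$pct_a_in_b, 0)
    if (max(ov) <= 0) return(NULL)
    data.frame(male_id = males[which.max(ov)], female_id = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full spatial-social analysis pipeline
#'
#' Reads the trajectory CSV (and optional sleeping / interaction / hours
#' CSVs), computes per-individual 95% kernel home ranges, pair and
#' same-sex neighbor overlap, the three dynamic-interaction tests per
#' dyad with Wilcoxon summaries across dyads, proximity time, and the
#' social-metric tables, and writes the report bundle under `outDir`:
#' `ranges.geojson`, `overlap_pairs.tsv`, `overlap_neighbors.tsv`,
#' `dyads.json`, `sleeping_tally.tsv`, `interaction_rates.tsv`, and
#' `run_log.txt` with all parameters. Deterministic given the inputs.
#'
#' @param trajectoriesCsv path to the trajectory CSV (see
#'   [readTrajectories()]).
#' @param outDir output directory, created if absent.
#' @param sleepingCsv,interactionsCsv,hoursCsv optional paths (see
#'   [readSleepRecords()], [readInteractions()]; hours CSV has columns
#'   `dyad, hours`).
#' @param pairs optional data.frame `male_id, female_id`; inferred from
#'   range overlap when `NULL`.
#' @param d,s distance criterion and group spread (m).
#' @param level isopleth level.
#' @param cell UD grid cell size (m).
#' @param bandwidth `"adhoc"` or `"reference"`.
#' @param alpha significance level.
#' @param subsample home-range fix interval (s).
#' @param independenceInterval Doncaster subsampling interval (s).
#' @param adjacency neighbor distance threshold (m).
#' @param alignTol dyad alignment tolerance (s).
#' @return invisibly, the in-memory report list.
#' @export
runPipeline <- function(trajectoriesCsv, outDir, sleepingCsv = NULL,
                        interactionsCsv = NULL, hoursCsv = NULL,
                        pairs = NULL, d = 15, s = 0, level = 0.95,
                        cell = 2.5, bandwidth = "adhoc", alpha = 0.05,
                        subsample = 300, independenceInterval = 1800,
                        adjacency = 50, alignTol = 150) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  trajs <- readTrajectories(trajectoriesCsv)
  ids <- unique(vapply(trajs, function(x) x@id, ""))
  pooled <- lapply(ids, function(id)
    poolTrajectories(Filter(function(x) x@id == id, trajs)))
  names(pooled) <- ids
  sexes <- vapply(pooled, function(x) x@sex, "")
  nights <- vapply(ids, function(id)
    length(unique(vapply(Filter(function(x) x@id == id, trajs),
                         function(x) x@night, ""))), 0)

  ranges <- lapply(pooled, homeRange, level = level, cell = cell,
                   bandwidth = bandwidth, subsample = subsample)
  writeRangesGeoJSON(ranges, file.path(outDir, "ranges.geojson"))

  if (is.null(pairs)) pairs <- .inferPairs(ranges, sexes)
  ovPairs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    percentOverlap(ranges[[pairs$female_id[i]]],
                   ranges[[pairs$male_id[i]]])))
  utils::write.table(ovPairs, file.path(outDir, "overlap_pairs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ovNb <- NULL
  for (sx in c("M", "F")) {
    same <- ranges[names(sexes)[sexes == sx]]
    if (length(same) >= 2)
      ovNb <- rbind(ovNb, overlapMatrix(same, neighborsOnly = TRUE,
                                        adjacency = adjacency))
  }
  if (is.null(ovNb)) ovNb <- overlapMatrix(ranges[0:0])
  utils::write.table(ovNb, file.path(outDir, "overlap_neighbors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  dyadReports <- lapply(seq_len(nrow(pairs)), function(i) {
    mId <- pairs$male_id[i]; fId <- pairs$female_id[i]
    dy <- alignDyad(pooled[[mId]], pooled[[fId]], tol = alignTol)
    rep <- dyadInteraction(dy, ranges[[mId]], ranges[[fId]],
                           pooled[[mId]], pooled[[fId]],
                           nights = max(nights[mId], nights[fId]),
                           d = d, s = s, subsample = subsample,
                           independenceInterval = independenceInterval,
                           alpha = alpha)
    rep$male_id <- mId; rep$female_id <- fId
    rep$doncaster$table <- NULL              # matrices don't serialize
    rep
  })
  gasW <- wilcoxonAcrossPairs(
    vapply(dyadReports, function(r) r$gas$observed, 0),
    vapply(dyadReports, function(r) r$gas$expected, 0))
  hutW <- wilcoxonAcrossPairs(
    vapply(dyadReports, function(r) r$hutchinson$observed, 0),
    vapply(dyadReports, function(r) r$hutchinson$expected, 0))
  dyadJson <- list(
    dyads = dyadReports,
    wilcoxon = list(
      gas = list(V = unname(gasW$statistic), n = unname(gasW$parameter),
                 p = gasW$p.value),
      hutchinson = list(V = unname(hutW$statistic),
                        n = unname(hutW$parameter), p = hutW$p.value)))
  jsonlite::write_json(dyadJson, file.path(outDir, "dyads.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- list(ranges = ranges, overlapPairs = ovPairs,
                 overlapNeighbors = ovNb, dyads = dyadJson)

  if (!is.null(sleepingCsv)) {
    tally <- sleepingTally(readSleepRecords(sleepingCsv), pairs)
    utils::write.table(tally, file.path(outDir, "sleeping_tally.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$sleeping <- tally
  }
  if (!is.null(interactionsCsv) && !is.null(hoursCsv)) {
    hrs <- utils::read.csv(hoursCsv, stringsAsFactors = FALSE)
    rt <- interactionRates(readInteractions(interactionsCsv), hrs)
    utils::write.table(
      cbind(rt$rates[, c("dyad", "neutral", "agonistic", "affiliative",
                         "total")],
            hours = rt$rates$hours),
      file.path(outDir, "interaction_rates.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    report$rates <- rt
  }

  log <- c(
    sprintf("dyadMove pipeline run: %s", format(Sys.time(), tz = "UTC")),
    sprintf("inputs: %s", trajectoriesCsv),
    sprintf("individuals: %s", paste(ids, collapse = ", ")),
    sprintf("parameters: d=%g m, s=%g m, level=%g, cell=%g m,", d, s,
            level, cell),
    sprintf("  bandwidth=%s, alpha=%g, subsample=%g s,", bandwidth,
            alpha, subsample),
    sprintf("  independenceInterval=%g s, adjacency=%g m, alignTol=%g s",
            independenceInterval, adjacency, alignTol))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(report)
}
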