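## Delimited-text and JSON I/O for event logs, configs and run summaries.

#' Read and write controller event logs
#'
#' Event logs are tab-delimited text with the columns produced by
#' [replayEvents()] / the simulator (`time_s`, `roi_id`, `state_before`,
#' `state_after`, `outcome`, `verdict`, `particle_id`). Round-trips are
#' lossless.
#'
#' @param log Event-log data.frame.
#' @param path File path.
#' @return `readEventLog` returns the data.frame; `writeEventLog` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' ev <- data.frame(time = 1, roi_id = 1, area = NA, xy_ratio = NA)
#' writeEventLog(replayEvents(ev, ControllerPolicy(), "SEEK"), f)
#' readEventLog(f)
#' @export
writeEventLog <- function(log, path) {
    write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Export the controller transition table
#'
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @examples
#' writeTransitionTable(tempfile(fileext = ".json"), "json")
#' @export
writeTransitionTable <- function(path, format = c("tsv", "json")) {
    format <- match.arg(format)
    tab <- transitionTable()
    if (format == "tsv")
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    else
        jsonlite::write_json(tab, path, pretty = TRUE)
    invisible(path)
}

#' Read a simulator configuration from a YAML/structured text file
#'
#' Keys mirror the arguments of [SimulationConfig()]; missing keys keep
#' their defaults.
#'
#' @param path Config file path.
#' @return A [SimulationConfig()].
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(SimulationConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("invalid config: unknown keys ", paste(unknown, collapse = ", "))
    do.call(SimulationConfig, vals)
}

#' Write a run summary
#'
#' Writes `events.tsv` (the state log), `loaded.tsv`, `rejected.tsv` and
#' `summary.json` with throughput, a bootstrap confidence interval over the
#' inter-load intervals, and state dwell-time tallies.
#'
#' @param result A [`SimResult`][SimResult-class].
#' @param dir Output directory (created if needed).
#' @param bootstrapN Bootstrap resamples for the throughput CI.
#' @param seed Seed for the bootstrap.
#' @return Invisibly, the summary list.
#' @export
writeRunSummary <- function(result, dir, bootstrapN = 200, seed = 1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeEventLog(eventLog(result), file.path(dir, "events.tsv"))
    write.table(loadedEvents(result), file.path(dir, "loaded.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rejectedEvents(result), file.path(dir, "rejected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    iv <- interLoadIntervals(result)
    ci <- if (length(iv) >= 2) {
        bs <- withSeed(seed, vapply(seq_len(bootstrapN), function(i)
            3600 / mean(sample(iv, replace = TRUE)), numeric(1)))
        unname(quantile(bs, c(0.025, 0.975)))
    } else c(NA_real_, NA_real_)
    log <- eventLog(result)
    dwell <- if (nrow(log) >= 2) {
        d <- diff(log$time_s)
        tapply(d, factor(log$state_after[-nrow(log)],
                         levels = fluidicStates()), sum, default = 0)
    } else stats::setNames(rep(0, 4), fluidicStates())
    summary <- list(
        mode = result@mode,
        duration_s = result@duration,
        n_loaded = nrow(loadedEvents(result)),
        n_rejected = nrow(rejectedEvents(result)),
        n_generated = result@nGenerated,
        n_remaining = result@nRemaining,
        overshoot_count = result@overshootCount,
        throughput_per_h = throughput(result),
        throughput_ci95 = ci,
        state_dwell_s = as.list(dwell))
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    invisible(summary)
}
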