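#' @keywords internal
"_PACKAGE"

#' @importFrom stats dhyper phyper p.adjust pt rnorm rnbinom rpois runif rlnorm
#'   sd setNames lm coef var aggregate
#' @importFrom utils read.delim read.table write.table
NULL

# stop() with a consistent prefix so pipeline errors name their stage
.fail <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}

.assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    .fail("config", "'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

.assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper) {
    .fail("config", "'%s' must be a single number in [%s, %s]", name, lower, upper)
  }
  as.numeric(x)
}

# timestamped message on stderr; every stage logs through this
.log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Write a tab-separated results table
#'
#' Plain-text TSV writer used for every table the pipeline emits
#' (no quoting, no row names), so outputs are diffable.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
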