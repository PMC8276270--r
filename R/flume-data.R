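#' Long-format repeated-measures flume dataset
#'
#' Container for one response variable observed across flumes, groups and
#' sampling times: a `data.frame` with columns `flume_id`, `group`
#' (`"control"` or `"treatment"`), `time_h` and `value`, carrying the
#' response name as an attribute.
#'
#' @param flume_id character or factor vector of flume identifiers.
#' @param group group labels, `"control"` or `"treatment"`.
#' @param time_h sampling time in hours from experiment start.
#' @param value observed response values.
#' @param response name of the response variable (e.g. `"doc"`, `"suva254"`).
#' @return A `flume_dataset` (a `data.frame` subclass).
#' @export
flume_dataset <- function(flume_id, group, time_h, value, response = "value") {
  group <- as.character(group)
  if (!all(group %in% c("control", "treatment")))
    abort_field("group", "labels must be 'control' or 'treatment'")
  if (!is.numeric(time_h) || any(!is.finite(time_h)) || any(time_h < 0))
    abort_field("time_h", "must be finite and nonnegative")
  if (!is.numeric(value) || any(!is.finite(value)))
    abort_field("value", "must be finite numeric")
  n <- length(value)
  if (length(flume_id) != n || length(group) != n || length(time_h) != n)
    abort_field("flume_dataset", "all columns must have equal length")
  df <- data.frame(flume_id = as.character(flume_id), group = group,
                   time_h = as.numeric(time_h), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  by_flume <- split(df$group, df$flume_id)
  if (any(vapply(by_flume, function(g) length(unique(g)) > 1L, logical(1))))
    abort_field("group", "each flume must belong to a single group")
  structure(df, response = response,
            class = c("flume_dataset", "data.frame"))
}

#' @export
print.flume_dataset <- function(x, ...) {
  cat(sprintf("<flume_dataset> response '%s': %d observations, %d flumes (%d control / %d treatment)\n",
              attr(x, "response"), nrow(x),
              length(unique(x$flume_id)),
              length(unique(x$flume_id[x$group == "control"])),
              length(unique(x$flume_id[x$group == "treatment"]))))
  NextMethod()
}

#' Read or write a flume dataset as long-format CSV
#'
#' The CSV layout is `flume_id, group, time_h, value`.
#'
#' @param x a [flume_dataset()].
#' @param path file path.
#' @param response response name recorded on read.
#' @return `read_flume_csv()` returns a `flume_dataset`;
#'   `write_flume_csv()` returns `path` invisibly.
#' @export
write_flume_csv <- function(x, path) {
  stopifnot(inherits(x, "flume_dataset"))
  utils::write.csv(as.data.frame(x)[, c("flume_id", "group", "time_h", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flume_csv
#' @export
read_flume_csv <- function(path, response = "value") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flume_id", "group", "time_h", "value")
  if (!all(need %in% names(df)))
    abort_field("path", sprintf("CSV must have columns %s", paste(need, collapse = ", ")))
  flume_dataset(df$flume_id, df$group, df$time_h, df$value, response = response)
}
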