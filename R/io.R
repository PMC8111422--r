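## Serialization and tidy exports.

#' Save a prepctrl object
#'
#' Networks, tasks, control laws and loop circuits are serialized with R's
#' native RDS format (exact round trip for integer and double payloads).
#'
#' @param object object to save.
#' @param file path.
#' @export
save_prepctrl <- function(object, file) {
  saveRDS(object, file)
  invisible(file)
}

#' Load a prepctrl object
#'
#' @param file path written by \code{\link{save_prepctrl}}.
#' @return the deserialized object.
#' @export
load_prepctrl <- function(file) readRDS(file)

#' Tidy export of a torque or trajectory tensor
#'
#' @param arr channel x time x condition array.
#' @param times time stamps (ms).
#' @param value_name name of the value column.
#' @return data.frame with columns time, condition, channel, value.
#' @export
tensor_to_df <- function(arr, times, value_name = "value") {
  d <- dim(arr)
  out <- data.frame(
    time = rep(times, each = d[1], times = d[3]),
    condition = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    value = as.numeric(arr))
  names(out)[4] <- value_name
  out
}
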