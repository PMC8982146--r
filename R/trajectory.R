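#' @export
print.ap_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("closed-loop trajectory: subject %s, scenario %s, preset %s, %d steps (%.1f h)\n",
              meta$subject, meta$scenario, meta$preset, nrow(x),
              nrow(x) * 5 / 60))
  m <- glycemic_metrics(x)
  cat(sprintf("  mean glucose %.1f mg/dL | TIR 63-140: %.1f%% | >140: %.1f%% | <63: %.1f%% | TDI %.1f U\n",
              m$mean_glucose, m$tir_63_140, m$above_140, m$below_63, m$tdi))
  invisible(x)
}

#' @export
summary.ap_trajectory <- function(object, ...) {
  glycemic_metrics(object)
}

#' Plot a closed-loop trajectory
#'
#' Two stacked panels: glucose (plasma and CGM) with the pregnancy target
#' range shaded, and commanded insulin with meal/bolus markers.
#'
#' @param x an `ap_trajectory`.
#' @param ... ignored.
#' @export
plot.ap_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$time / 60
  graphics::plot(h, x$G, type = "n", ylab = "glucose (mg/dL)", xlab = "",
                 ylim = range(c(x$G, x$cgm, 50, 200)),
                 main = sprintf("%s / %s / %s", meta$subject, meta$scenario,
                                meta$preset))
  graphics::rect(0, 63, max(h), 140, col = "#dff0df", border = NA)
  graphics::lines(h, x$cgm, col = "grey60")
  graphics::lines(h, x$G, col = "black", lwd = 1.5)
  graphics::abline(v = x$time[x$meal > 0] / 60, col = "orange", lty = 3)
  graphics::plot(h, x$u * 12, type = "s", ylab = "insulin (U/h)",
                 xlab = "hours", col = "steelblue")
  graphics::points(h[x$bolus > 0], x$bolus[x$bolus > 0] * 12, pch = 17,
                   col = "red")
  invisible(x)
}

## trajectory CSV schema version written in the header comment
.traj_schema <- "apzone-trajectory-v1"

#' Write / read a trajectory as CSV
#'
#' Plain CSV with a commented metadata header (schema version, subject,
#' scenario, preset, seed, basal, CR, CF). Dose records are recoverable from
#' the `u`, `u_basal` and `bolus` columns.
#'
#' @param traj an `ap_trajectory`.
#' @param file path.
#' @export
write_trajectory <- function(traj, file) {
  meta <- attr(traj, "meta")
  hdr <- sprintf("# %s subject=%s scenario=%s preset=%s seed=%s basal_h=%.17g cr=%.17g cf=%.17g tdi=%.17g start_clock=%g closed_start=%g noise=%s",
                 .traj_schema, meta$subject, meta$scenario, meta$preset,
                 meta$seed, meta$basal_h, meta$cr, meta$cf, meta$tdi_nominal,
                 meta$start_clock, meta$closed_start, meta$noise)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(unclass(traj))[, c("time", "clock", "G",
    "cgm", "u", "u_basal", "bound", "bolus", "meal")], con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  hdr <- readLines(file, n = 1)
  if (!startsWith(hdr, paste0("# ", .traj_schema)))
    stop("not an ", .traj_schema, " file: ", file)
  kv <- strsplit(sub("^# \\S+ ", "", hdr), " ")[[1]]
  kv <- strsplit(kv, "=")
  meta <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  for (f in c("seed", "basal_h", "cr", "cf", "tdi", "start_clock",
              "closed_start"))
    meta[[f]] <- as.numeric(meta[[f]])
  names(meta)[names(meta) == "tdi"] <- "tdi_nominal"
  traj <- utils::read.csv(file, comment.char = "#")
  attr(traj, "meta") <- meta
  class(traj) <- c("ap_trajectory", "data.frame")
  traj
}
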