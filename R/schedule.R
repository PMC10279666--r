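#' Create a cyclic cosine-annealing schedule configuration
#'
#' The schedule divides `total_epochs` into `num_cycles` equal cycles. Within
#' a cycle the learning rate decays along a half cosine from `initial_rate`
#' to near zero, then resets to `initial_rate` at the next cycle start; the
#' reset perturbs the weights enough to escape the minimum the model
#' converged to, and the model state at each cycle end is saved as one
#' snapshot of the ensemble.
#'
#' @param initial_rate positive numeric, the rate \eqn{\alpha_0} at each
#'   cycle start. Default `2e-4`.
#' @param total_epochs positive integer \eqn{E}. Default 100.
#' @param num_cycles positive integer \eqn{C}; must divide `total_epochs`
#'   exactly. Default 5.
#' @return a [ScheduleConfig-class] object.
#' @examples
#' cfg <- scheduleConfig(2e-4, 100, 5)
#' learningRate(cfg, 1)      # 2e-4 at the first epoch of a cycle
#' snapshotEpochs(cfg)       # 20 40 60 80 100
#' @export
scheduleConfig <- function(initial_rate = 2e-4, total_epochs = 100L,
                           num_cycles = 5L) {
  new("ScheduleConfig",
      initial_rate = as.numeric(initial_rate),
      total_epochs = as.integer(total_epochs),
      num_cycles = as.integer(num_cycles))
}

#' Learning rate at a given epoch
#'
#' Evaluates the closed-form cyclic cosine-annealing schedule
#' \deqn{\alpha(t) = \frac{\alpha_0}{2}\left(\cos\!\left(\frac{\pi\,
#' \mathrm{mod}(t-1, E/C)}{E/C}\right) + 1\right)}
#' with 1-based epoch index `t`. The schedule is epoch-granular: it is
#' applied once per epoch, not per batch.
#'
#' @param config a [ScheduleConfig-class].
#' @param epoch integer epoch `t`, `1 <= t <= total_epochs`. Vectorised.
#' @return the learning rate(s), in `(0, initial_rate]`.
#' @rdname learningRate
#' @export
setMethod("learningRate", "ScheduleConfig", function(config, epoch) {
  validObject(config)
  epoch <- as.numeric(epoch)
  E <- config@total_epochs
  if (any(epoch < 1 | epoch > E | epoch != floor(epoch)))
    stop("epoch must be an integer in [1, total_epochs]")
  len <- E / config@num_cycles
  config@initial_rate / 2 * (cos(pi * ((epoch - 1) %% len) / len) + 1)
})

#' Epochs at which snapshots are taken
#'
#' A snapshot is saved at the last epoch of each cycle, i.e. at the
#' multiples of `total_epochs / num_cycles`.
#'
#' @param config a [ScheduleConfig-class].
#' @return strictly increasing integer vector of length `num_cycles`,
#'   ending at `total_epochs`.
#' @rdname snapshotEpochs
#' @export
setMethod("snapshotEpochs", "ScheduleConfig", function(config) {
  validObject(config)
  len <- config@total_epochs %/% config@num_cycles
  seq.int(len, config@total_epochs, by = len)
})

#' Tabulate (and optionally export) the full schedule
#'
#' @param config a [ScheduleConfig-class].
#' @param file optional path; when given, the table is written as CSV
#'   (columns `epoch`, `learning_rate`) for plotting.
#' @return invisibly (when writing) or visibly a data.frame of the
#'   per-epoch learning rates.
#' @rdname scheduleTable
#' @export
setMethod("scheduleTable", "ScheduleConfig", function(config, file = NULL) {
  epochs <- seq_len(config@total_epochs)
  tab <- data.frame(epoch = epochs, learning_rate = learningRate(config, epochs))
  if (!is.null(file)) {
    write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
})

setMethod("show", "ScheduleConfig", function(object) {
  cat(sprintf(
    "ScheduleConfig: alpha0 = %g, E = %d epochs, C = %d cycles (%d epochs/cycle)\n",
    object@initial_rate, object@total_epochs, object@num_cycles,
    object@total_epochs %/% object@num_cycles))
  cat("snapshot epochs:", paste(snapshotEpochs(object), collapse = ", "), "\n")
})
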