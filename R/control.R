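# Safety layer between classifier output and motor commands. Even a
# well-trained classifier misclassifies in the field; the state machine
# rejects unsafe transitions (no direct reversal between opposing
# motions) and the debouncer suppresses transient misclassifications.

#' Drive states of the safety state machine
#' @export
drive_states <- c("off", "neutral", "forward", "backward", "left", "right")

motion_states <- c("forward", "backward", "left", "right")

#' Next state of the safety state machine
#'
#' Transition rules:
#' * `off` responds only to `switch_on` (to `neutral`);
#' * `switch_off` turns the machine off from any state (emergency stop);
#' * `neutral` accepts any motion command;
#' * a motion state accepts only `neutral` (stop) or its own command —
#'   every other motion command, in particular the opposing one
#'   (forward/backward, left/right), is rejected and the state is
#'   unchanged, so a reversal always passes through neutral;
#' * anything unrecognised leaves the state unchanged.
#'
#' Unsafe requests are rejections, never errors: the function is total.
#'
#' @param state current state, one of [drive_states].
#' @param cmd classified command, one of [command_classes].
#' @return the next state.
#' @export
next_state <- function(state, cmd) {
  state <- match.arg(state, drive_states)
  cmd <- match.arg(cmd, command_classes)
  if (cmd == "switch_off") return("off")
  if (state == "off") return(if (cmd == "switch_on") "neutral" else "off")
  if (cmd == "neutral") return("neutral")
  if (state == "neutral" && cmd %in% motion_states) return(cmd)
  if (state %in% motion_states && cmd == state) return(state)
  state
}

#' Debounce a stream of classified commands
#'
#' A command is acted on only once it has been observed `k` times in
#' immediate succession; any differing command resets the run. `k = 1`
#' passes every command through.
#'
#' @param commands character vector of classified commands, in time
#'   order.
#' @param k consecutive identical classifications required (default 3).
#' @return data frame with `position` (1-based index into the stream)
#'   and `command` for every accepted command.
#' @export
debounce <- function(commands, k = 3L) {
  if (k < 1L) abort("k must be at least 1", "fnnbci_bad_k")
  run <- 0L; prev <- NA_character_
  pos <- integer(0); out <- character(0)
  for (i in seq_along(commands)) {
    run <- if (identical(commands[i], prev)) run + 1L else 1L
    prev <- commands[i]
    if (run >= k) {
      pos <- c(pos, i)
      out <- c(out, commands[i])
    }
  }
  data.frame(position = pos, command = out)
}

#' Simulate a drive through the safety layer
#'
#' Feeds a time-ordered command stream through [debounce()] and
#' [next_state()], starting from `init`, and records the trajectory.
#'
#' @param commands character vector of per-window classified commands.
#' @param k debounce count (default 3).
#' @param init initial state (default `"off"`).
#' @param timestamps optional window start times (seconds).
#' @return data frame with one row per input command: `timestamp`,
#'   `command`, `accepted` (passed the debouncer), `state` (after the
#'   step).
#' @export
simulate_drive <- function(commands, k = 3L, init = "off",
                           timestamps = NULL) {
  state <- match.arg(init, drive_states)
  acc <- debounce(commands, k)
  accepted <- seq_along(commands) %in% acc$position
  states <- character(length(commands))
  for (i in seq_along(commands)) {
    if (accepted[i]) state <- next_state(state, commands[i])
    states[i] <- state
  }
  data.frame(
    timestamp = if (is.null(timestamps)) seq_along(commands) - 1L
                else timestamps,
    command = commands, accepted = accepted, state = states)
}
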