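#' The 13-mode lower-limb locomotion taxonomy
#'
#' Five steady-state modes — level walking (LW), stair ascent/descent (SA/SD) and
#' ramp ascent/descent (RA/RD) — plus the eight transition patterns between level
#' walking and the other four terrains. Transition codes are written
#' `<from>-<to>`, e.g. `"RD-LW"` is the phase change from ramp descent to level
#' walking.
#'
#' @return A tibble with one row per mode: `code` (character identifier),
#'   `is_transition` (logical), and for transitions `from`/`to` (the two steady
#'   phases, `NA` for steady modes). Row order is the canonical ordering used for
#'   confusion matrices.
#' @examples
#' locomotion_modes()
#' @export
locomotion_modes <- function() {
  steady <- c("LW", "SA", "SD", "RA", "RD")
  trans <- c("LW-SA", "LW-SD", "LW-RA", "LW-RD", "RA-LW", "RD-LW", "SA-LW", "SD-LW")
  parts <- strsplit(trans, "-", fixed = TRUE)
  tibble::tibble(
    code = c(trans, steady),
    is_transition = c(rep(TRUE, 8), rep(FALSE, 5)),
    from = c(vapply(parts, `[`, "", 1L), rep(NA_character_, 5)),
    to = c(vapply(parts, `[`, "", 2L), rep(NA_character_, 5))
  )
}

#' @rdname locomotion_modes
#' @export
mode_codes <- function() locomotion_modes()$code

assert_mode <- function(code) {
  bad <- setdiff(code, mode_codes())
  if (length(bad) > 0) {
    abort(paste0("unknown locomotion mode(s): ", paste(bad, collapse = ", ")))
  }
  invisible(code)
}
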