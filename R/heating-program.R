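#' Heating programs
#'
#' A heating program is an ordered list of temperature-versus-time segments,
#' each either an isothermal hold or a linear ramp. Programs describe the
#' thermal exposure of a sample: the 3-minute single-temperature steps of a
#' conventional TPP ladder, the continuous 37 degC -> T_max ramp of an
#' STPP-UP experiment, or an isothermal incubation at T_max.
#'
#' @param ... segments built with [hp_hold()] or [hp_ramp()], or a single list
#'   of such segments.
#' @return An object of class `heating_program`.
#' @examples
#' heating_program(hp_hold(37, 5), hp_ramp(37, 57, 0.2))
#' @export
heating_program <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) && !inherits(segs[[1]], "hp_segment")) {
    segs <- segs[[1]]
  }
  if (length(segs) == 0L) {
    ts_error("a heating program needs at least one segment", "invalid_program")
  }
  for (s in segs) {
    if (!inherits(s, "hp_segment")) {
      ts_error("heating program segments must be built with hp_hold() or hp_ramp()",
               "invalid_program")
    }
  }
  structure(list(segments = segs), class = "heating_program")
}

#' @rdname heating_program
#' @param temperature,duration hold temperature (degC, in \[0, 100\]) and
#'   duration (s, > 0).
#' @export
hp_hold <- function(temperature, duration) {
  stopifnot(is.numeric(temperature), is.numeric(duration))
  if (!is.finite(temperature) || temperature < 0 || temperature > 100) {
    ts_error("hold temperature must be in [0, 100] degC", "invalid_program")
  }
  if (!is.finite(duration) || duration <= 0) {
    ts_error("hold duration must be finite and > 0", "invalid_program")
  }
  structure(list(kind = "hold", temperature = temperature, duration = duration),
            class = "hp_segment")
}

#' @rdname heating_program
#' @param from,to,rate ramp start and end temperatures (degC, `to > from`) and
#'   heating rate (degC/s, > 0).
#' @export
hp_ramp <- function(from, to, rate) {
  stopifnot(is.numeric(from), is.numeric(to), is.numeric(rate))
  if (!all(is.finite(c(from, to, rate)))) {
    ts_error("ramp parameters must be finite", "invalid_program")
  }
  if (from < 0 || from > 100 || to < 0 || to > 100) {
    ts_error("ramp temperatures must be in [0, 100] degC", "invalid_program")
  }
  if (rate <= 0) ts_error("ramp rate must be > 0", "invalid_program")
  if (to <= from) ts_error("ramp end temperature must exceed its start", "invalid_program")
  structure(list(kind = "ramp", from = from, to = to, rate = rate),
            class = "hp_segment")
}

#' Named constructors for the three standard programs
#'
#' `tpp_step()` is a single 3-minute hold at one ladder temperature;
#' `stpp_ramp()` is a 5 s equilibration at 37 degC followed by a linear ramp to
#' `t_max`; `isothermal_hold()` is a 3-minute hold at `t_max`, the constant
#' incubation the ramp is compared against.
#'
#' @param temperature,t_max temperatures in degC.
#' @param rate ramp rate in degC/s.
#' @param duration hold duration in seconds.
#' @return A `heating_program`.
#' @export
tpp_step <- function(temperature, duration = 180) {
  heating_program(hp_hold(temperature, duration))
}

#' @rdname tpp_step
#' @export
stpp_ramp <- function(t_max = 57, rate = 0.2) {
  heating_program(hp_hold(37, 5), hp_ramp(37, t_max, rate))
}

#' @rdname tpp_step
#' @export
isothermal_hold <- function(t_max = 57, duration = 180) {
  heating_program(hp_hold(t_max, duration))
}

#' Total duration of a heating program in seconds
#' @param program a `heating_program`.
#' @export
program_duration <- function(program) {
  stopifnot(inherits(program, "heating_program"))
  sum(vapply(program$segments, segment_duration, numeric(1)))
}

segment_duration <- function(seg) {
  if (seg$kind == "hold") seg$duration else (seg$to - seg$from) / seg$rate
}

#' Concatenate heating programs
#' @param ... `heating_program` objects, applied in order.
#' @export
hp_concat <- function(...) {
  programs <- list(...)
  heating_program(do.call(c, lapply(programs, function(p) {
    stopifnot(inherits(p, "heating_program"))
    p$segments
  })))
}

#' Build a heating program from a config-style segment list
#'
#' Accepts the YAML-friendly representation used in run configs: a list of
#' segments, each a list with `kind: hold` (fields `temperature`, `duration`)
#' or `kind: ramp` (fields `from`, `to`, `rate`).
#'
#' @param x a list of segment lists.
#' @export
as_heating_program <- function(x) {
  if (inherits(x, "heating_program")) return(x)
  stopifnot(is.list(x))
  segs <- lapply(x, function(s) {
    if (is.null(s$kind)) ts_error("segment without a 'kind' field", "invalid_program")
    switch(s$kind,
      hold = hp_hold(s$temperature, s$duration),
      ramp = hp_ramp(s$from, s$to, s$rate),
      ts_error(sprintf("unknown segment kind '%s'", s$kind), "invalid_program")
    )
  })
  heating_program(segs)
}

#' @export
print.heating_program <- function(x, ...) {
  cat(sprintf("<heating_program: %d segment(s), %.1f s total>\n",
              length(x$segments), program_duration(x)))
  for (s in x$segments) {
    if (s$kind == "hold") {
      cat(sprintf("  hold %.1f degC for %.1f s\n", s$temperature, s$duration))
    } else {
      cat(sprintf("  ramp %.1f -> %.1f degC at %.3f degC/s\n", s$from, s$to, s$rate))
    }
  }
  invisible(x)
}
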