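#' Instruction maps for the two stepping-controlled devices
#'
#' Maps each expression class to a device instruction. The state-switching
#' class `s-RB` never maps to an instruction and `NON` means hold-on.
#' Robotic-arm steppings: Right +X 30 mm, Left -X 2 mm, Forward +Y 20 mm,
#' Backward -Y 3 mm, Up +Z 30 mm, Down -Z 10 mm while Z > 21 mm else 3 mm,
#' Open releases the gripper. Prosthetic-hand steppings: Open 7.0 mm,
#' Close 10.5 mm, Extorsion 11.0 deg, Intorsion 12.0 deg; classes disabled
#' for the task are absent from the map.
#'
#' @param device `"arm"` or `"hand"`.
#' @return An `instruction_map`: named character vector (class ->
#'   instruction), `NA` meaning no mapping.
#' @export
instruction_map <- function(device = c("arm", "hand")) {
  device <- match.arg(device)
  values <- switch(device,
    arm = c("s-FB" = "Open", "s-LS" = "Left", "s-RS" = "Right",
            "s-OM" = "Up", "s-S" = "Down", "s-PM" = "Backward",
            "s-DM" = "Forward"),
    hand = c("s-FB" = "Open", "s-LS" = "Extorsion", "s-RS" = "Intorsion",
             "s-S" = "Close")
  )
  structure(values, device = device, class = "instruction_map")
}

#' Virtual robotic-arm adapter
#'
#' Integrates stepping instructions into an x/y/z position (mm) and gripper
#' state, including the Z-dependent "Down" stepping (10 mm while Z > 21 mm,
#' 3 mm otherwise).
#'
#' @param x,y,z Initial position in mm.
#' @return A `device_adapter` environment with `$state()` accessor.
#' @export
virtual_arm <- function(x = 0, y = 0, z = 30) {
  env <- new.env(parent = emptyenv())
  env$x <- x; env$y <- y; env$z <- z; env$gripper <- "closed"
  env$log <- character(0)
  env$send <- function(instruction) {
    switch(instruction,
      Right = env$x <- env$x + 30,
      Left = env$x <- env$x - 2,
      Forward = env$y <- env$y + 20,
      Backward = env$y <- env$y - 3,
      Up = env$z <- env$z + 30,
      Down = env$z <- env$z - if (env$z > 21) 10 else 3,
      Open = env$gripper <- "open",
      stop(sprintf("unknown arm instruction '%s'", instruction), call. = FALSE)
    )
    env$log <- c(env$log, instruction)
    list(ok = TRUE, instruction = instruction)
  }
  env$state <- function() list(x = env$x, y = env$y, z = env$z,
                               gripper = env$gripper)
  class(env) <- c("device_adapter", "environment")
  env
}

#' Virtual prosthetic-hand adapter
#'
#' Integrates palm aperture (mm, clamped to \[0, 95\]) and wrist angle
#' (degrees) under stepping control.
#'
#' @param aperture Initial palm aperture in mm (95 = fully open).
#' @param angle Initial wrist angle in degrees.
#' @return A `device_adapter` environment with `$state()` accessor.
#' @export
virtual_hand <- function(aperture = 95, angle = 0) {
  env <- new.env(parent = emptyenv())
  env$aperture <- aperture; env$angle <- angle
  env$log <- character(0)
  env$send <- function(instruction) {
    switch(instruction,
      Open = env$aperture <- min(95, env$aperture + 7.0),
      Close = env$aperture <- max(0, env$aperture - 10.5),
      Extorsion = env$angle <- env$angle + 11.0,
      Intorsion = env$angle <- env$angle - 12.0,
      stop(sprintf("unknown hand instruction '%s'", instruction), call. = FALSE)
    )
    env$log <- c(env$log, instruction)
    list(ok = TRUE, instruction = instruction)
  }
  env$state <- function() list(aperture = env$aperture, angle = env$angle)
  class(env) <- c("device_adapter", "environment")
  env
}

#' Send one instruction to a device adapter
#'
#' @param instruction Instruction name (see [instruction_map()]).
#' @param adapter A `device_adapter`.
#' @return The adapter's acknowledgment (list with `ok` and `instruction`).
#' @export
emit <- function(instruction, adapter) {
  adapter$send(instruction)
}
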