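#' Race section types
#' @return Character vector of the four section types.
#' @export
section_types <- function() c("right", "headlight", "left", "noinput")

#' Generate a randomized 16-section race track
#'
#' A seeded uniform permutation of the 4+4+4+4 multiset of section types:
#' every track has exactly 16 sections with exactly four of each type.
#'
#' @param seed integer RNG seed.
#' @return Character vector of length 16 with class `race_track`.
#' @export
generate_track <- function(seed = 1L) {
  sections <- rep(section_types(), each = 4)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  structure(sample(sections), class = "race_track")
}

# Internal: save/restore the global RNG state so seeded helpers do not
# perturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
set_rng_state <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Map BCI commands to game commands
#'
#' Both-hands commands steer left, both-feet commands steer right. The
#' headlight command uses a sequential strategy: when a delivered game
#' command is followed within `headlight_window` seconds by a BCI command
#' of the opposite type, a `headlight` is emitted instead of that second
#' command. No BCI command means no game input (the intentional
#' non-control state).
#'
#' @param commands data.frame with columns `time` (increasing seconds) and
#'   `class` (`both_hands` / `both_feet`).
#' @param headlight_window interval for the sequential headlight rule, s
#'   (default 2).
#' @return data.frame `time`, `command` (`left`, `right`, `headlight`).
#' @export
map_to_game <- function(commands, headlight_window = 2) {
  if (nrow(commands) == 0) {
    return(data.frame(time = numeric(0), command = character(0)))
  }
  if (is.unsorted(commands$time, strictly = FALSE)) {
    stop("command timestamps must be increasing")
  }
  base_map <- c(both_hands = "left", both_feet = "right")
  out_cmd <- character(nrow(commands))
  prev_class <- NA_character_
  prev_time <- -Inf
  for (i in seq_len(nrow(commands))) {
    cl <- as.character(commands$class[i])
    tm <- commands$time[i]
    if (!is.na(prev_class) && cl != prev_class &&
        tm - prev_time <= headlight_window) {
      out_cmd[i] <- "headlight"
    } else {
      out_cmd[i] <- base_map[[cl]]
    }
    prev_class <- cl
    prev_time <- tm
  }
  data.frame(time = commands$time, command = out_cmd)
}

#' Race kinematics configuration
#'
#' The game binary's true kinematics are not public; these configurable
#' defaults preserve the orderings that matter (correct command > no
#' command > wrong command) and are chosen so that a perfect pilot
#' finishes a 16-section track in about 110 s while a silent pilot hits
#' the 240 s cap.
#'
#' @param section_length section length, arbitrary units (default 16).
#' @param base_speed cruising speed, units/s (default 1).
#' @param boost_speed speed for the rest of a section after its correct
#'   command (default 4).
#' @param penalty_speed speed during a penalty (default 0.5).
#' @param penalty_duration penalty length after a wrong command, s
#'   (default 2).
#' @param time_cap maximum race time, s (default 240).
#' @return list of class `race_kinematics`.
#' @export
race_kinematics <- function(section_length = 16, base_speed = 1,
                            boost_speed = 4, penalty_speed = 0.5,
                            penalty_duration = 2, time_cap = 240) {
  stopifnot(base_speed > 0, boost_speed > 0, penalty_speed > 0)
  structure(list(section_length = section_length, base_speed = base_speed,
                 boost_speed = boost_speed, penalty_speed = penalty_speed,
                 penalty_duration = penalty_duration, time_cap = time_cap),
            class = "race_kinematics")
}

#' Simulate a race
#'
#' Advances the avatar through the track. In an active section the first
#' matching game command switches the avatar to boost speed for the rest
#' of that section; a non-matching command (and any command inside a
#' noinput section) triggers a penalty interval at penalty speed. Input is
#' either a pre-computed game-command log or a pilot policy: a per-section
#' command-accuracy probability with a seed, under which the pilot
#' attempts the correct command at each active-section entry (emitting a
#' wrong one otherwise) and stays silent in noinput sections with the same
#' probability.
#'
#' @param input either a data.frame of game commands (`time`, `command`)
#'   or a list `list(accuracy = , seed = , react = )` pilot policy
#'   (`react`: reaction delay after section entry, default 0.5 s).
#' @param track a `race_track`.
#' @param kin a `race_kinematics`.
#' @return list of class `race_result`: `time` (capped completion time,
#'   s), `complete` (logical), `section_times` (per-section crossing
#'   times; for an incomplete race the unfinished section absorbs the
#'   remaining time), `log` (data.frame of commands with correctness).
#' @export
simulate_race <- function(input, track, kin = race_kinematics()) {
  stopifnot(length(track) == 16)
  policy <- !is.data.frame(input)
  if (policy) {
    acc <- input$accuracy
    react <- if (is.null(input$react)) 0.5 else input$react
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(if (is.null(input$seed)) 1L else input$seed)
    draws <- stats::runif(length(track))
  }
  t_now <- 0
  log_t <- numeric(0)
  log_c <- character(0)
  log_ok <- logical(0)
  section_times <- numeric(length(track))
  complete <- TRUE
  for (s in seq_along(track)) {
    sec <- track[s]
    t_enter <- t_now
    remaining <- kin$section_length
    boosted <- FALSE
    if (policy) {
      correct <- draws[s] < acc
      if (sec == "noinput") {
        cmds <- if (correct) {
          data.frame(time = numeric(0), command = character(0))
        } else {
          data.frame(time = t_enter + react, command = "left")
        }
      } else {
        cmds <- data.frame(
          time = t_enter + react,
          command = if (correct) sec else
            sample(setdiff(section_types(), c(sec, "noinput")), 1))
      }
    } else {
      cmds <- input[input$time >= t_enter, , drop = FALSE]
    }
    ci <- 1L
    repeat {
      speed <- if (boosted) kin$boost_speed else kin$base_speed
      nxt_cmd <- if (ci <= nrow(cmds) && !boosted) cmds$time[ci] else Inf
      t_exit <- t_now + remaining / speed
      if (nxt_cmd < t_exit && nxt_cmd >= t_now) {
        remaining <- remaining - speed * (nxt_cmd - t_now)
        t_now <- nxt_cmd
        cmd <- cmds$command[ci]
        ok <- sec != "noinput" && cmd == sec
        log_t <- c(log_t, t_now)
        log_c <- c(log_c, cmd)
        log_ok <- c(log_ok, ok)
        if (ok) {
          boosted <- TRUE
        } else {
          # penalty interval at penalty speed (capped at section end)
          pen_end <- t_now + kin$penalty_duration
          dist_pen <- kin$penalty_speed * kin$penalty_duration
          if (dist_pen >= remaining) {
            t_now <- t_now + remaining / kin$penalty_speed
            remaining <- 0
          } else {
            remaining <- remaining - dist_pen
            t_now <- pen_end
          }
        }
        ci <- ci + 1L
        if (remaining <= 0) break
      } else {
        t_now <- t_exit
        remaining <- 0
        break
      }
      if (t_now >= kin$time_cap) break
    }
    if (t_now >= kin$time_cap) {
      # cap reached: run marked incomplete, current section absorbs the
      # remaining capped time
      section_times[s] <- kin$time_cap - t_enter
      t_now <- kin$time_cap
      complete <- FALSE
      break
    }
    section_times[s] <- t_now - t_enter
  }
  structure(
    list(time = t_now, complete = complete,
         section_times = stats::setNames(section_times, track),
         log = data.frame(time = log_t, command = log_c,
                          correct = log_ok)),
    class = "race_result"
  )
}

#' @export
print.race_result <- function(x, ...) {
  cat(sprintf("<race_result> %.1f s (%s), %d commands\n", x$time,
              if (x$complete) "complete" else "capped/incomplete",
              nrow(x$log)))
  invisible(x)
}
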