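#' Define a divergence scenario
#'
#' A scenario is a rooted history of population splits, specified backward in
#' time as a sequence of merge events. Each event folds a derived population
#' into its ancestral population at a time given in generations; after the
#' last event a single ancestral lineage remains. Effective sizes are diploid
#' individuals per population label; the branch surviving a merge keeps the
#' ancestral label's size.
#'
#' @param name scenario identifier
#' @param events data frame with columns `time` (generations, > 0), `derived`
#'   and `ancestral` (population labels), ordered backward in time
#' @param sizes named numeric vector of diploid effective sizes, one entry per
#'   leaf label
#' @param leaves character vector of leaf labels; defaults to the labels
#'   appearing in `events`
#' @return an object of class `scenario`
#' @examples
#' scenario("two_pops",
#'          events = data.frame(time = 1e5, derived = "B", ancestral = "A"),
#'          sizes = c(A = 1e4, B = 1e4))
#' @export
scenario <- function(name, events, sizes, leaves = NULL) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("time", "derived", "ancestral") %in% names(events)))
  events$time <- as.numeric(events$time)
  events$derived <- as.character(events$derived)
  events$ancestral <- as.character(events$ancestral)
  if (is.null(leaves)) {
    leaves <- sort(unique(c(events$derived, events$ancestral)))
  }
  obj <- structure(
    list(name = name, leaves = leaves, events = events, sizes = sizes),
    class = "scenario"
  )
  validate_scenario(obj)
  obj
}

#' Validate a scenario's internal consistency
#'
#' Checks that event times strictly increase backward in time, that every
#' population merges at most once (and all but one exactly once), that all
#' effective sizes are positive, and that exactly one root lineage remains.
#'
#' @param x a [scenario()] object
#' @return `x`, invisibly; errors on violation
#' @export
validate_scenario <- function(x) {
  stopifnot(inherits(x, "scenario"))
  ev <- x$events
  if (nrow(ev) == 0) {
    if (length(x$leaves) != 1) {
      stop("scenario without events must have a single leaf", call. = FALSE)
    }
  } else {
    if (any(ev$time <= 0)) stop("event times must be positive", call. = FALSE)
    if (is.unsorted(ev$time)) {
      stop("events must be ordered backward in time", call. = FALSE)
    }
    if (anyDuplicated(ev$derived)) {
      stop("a population may merge only once", call. = FALSE)
    }
    if (any(ev$derived == ev$ancestral)) {
      stop("a population cannot merge into itself", call. = FALSE)
    }
    # along any root path times must strictly increase: a later event touching
    # the lineage produced by an earlier one cannot share its time
    for (i in seq_len(nrow(ev))) {
      dep <- which(
        seq_len(nrow(ev)) > i &
          (ev$derived == ev$ancestral[i] | ev$ancestral == ev$ancestral[i])
      )
      if (length(dep) && any(ev$time[dep] <= ev$time[i])) {
        stop("event times must strictly increase along any root path",
             call. = FALSE)
      }
    }
  }
  unknown <- setdiff(c(ev$derived, ev$ancestral), x$leaves)
  if (length(unknown)) {
    stop("event references unknown population(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # a derived label must not be used after it has merged away
  gone <- character()
  for (i in seq_len(nrow(ev))) {
    if (ev$derived[i] %in% gone || ev$ancestral[i] %in% gone) {
      stop("event ", i, " references a population that already merged",
           call. = FALSE)
    }
    gone <- c(gone, ev$derived[i])
  }
  if (length(setdiff(x$leaves, gone)) != 1) {
    stop("history must leave exactly one root lineage; ",
         length(setdiff(x$leaves, gone)), " remain", call. = FALSE)
  }
  missing_sizes <- setdiff(x$leaves, names(x$sizes))
  if (length(missing_sizes)) {
    stop("missing effective size for: ", paste(missing_sizes, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$sizes[x$leaves] <= 0)) stop("all N_e must be > 0", call. = FALSE)
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n", sep = "")
  cat("  leaves: ", paste(x$leaves, collapse = ", "), "\n", sep = "")
  cat("  root:   ", scenario_root(x), "\n", sep = "")
  for (i in seq_len(nrow(x$events))) {
    cat(sprintf("  t = %g: %s -> %s\n", x$events$time[i],
                x$events$derived[i], x$events$ancestral[i]))
  }
  invisible(x)
}

#' Root population of a scenario
#' @param x a [scenario()] object
#' @return the label of the population surviving all merges
#' @export
scenario_root <- function(x) {
  setdiff(x$leaves, x$events$derived)
}

#' Number of merge depth levels in a scenario
#'
#' The length of the longest chain of dependent merge events (an event depends
#' on an earlier one when it involves the lineage the earlier merge produced).
#' Two independent cherries followed by a root join give two levels; a fully
#' pectinate history of k merges gives k.
#' @param x a [scenario()] object
#' @return integer
#' @export
scenario_depth <- function(x) {
  ev <- x$events
  n <- nrow(ev)
  if (n == 0) return(0L)
  depth <- rep(1L, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    prev <- seq_len(i - 1)
    feeds <- prev[ev$ancestral[prev] %in% c(ev$derived[i], ev$ancestral[i])]
    if (length(feeds)) depth[i] <- max(depth[feeds]) + 1L
  }
  max(depth)
}

#' Built-in divergence scenarios for the four-region study design
#'
#' Three competing histories for the Black Forest (BF), Massif Central (MC),
#' Pyrenees (PY) and Cantabrian Mountains (CM) populations:
#'
#' * scenario 6 — vicariance: an ancestral split between a northern
#'   (MC + BF) and a southern (CM + PY) group, `((CM,PY),(MC,BF))`;
#' * scenario 17 — gradual northward colonization from the Cantabrian
#'   Mountains via the Pyrenees and Massif Central, `(CM,(PY,(MC,BF)))`;
#' * scenario 20 — like 17 but with the Pyrenees as the most ancestral
#'   population, `(PY,(CM,(MC,BF)))`.
#'
#' Split times default to clock-informed values (in generations, one
#' generation per year): MC/BF at 2.1e5, the mid-level split at 9.25e5 and the
#' deepest at 1.5e6 where applicable; effective sizes default to larger
#' populations in the diverse southern regions. All can be overridden.
#'
#' @param t1,t2,t3 split times in generations, youngest to oldest
#' @param sizes named vector of diploid effective sizes for BF, MC, PY, CM
#' @return `scenario_library()` returns a named list of `scenario` objects;
#'   the individual constructors return one scenario
#' @export
scenario_library <- function() {
  list(s6 = scenario_6(), s17 = scenario_17(), s20 = scenario_20())
}

default_sizes <- function() {
  c(BF = 20000, MC = 80000, PY = 30000, CM = 100000)
}

#' @rdname scenario_library
#' @export
scenario_6 <- function(t1 = 2.0e5, t2 = 2.1e5, t3 = 9.25e5,
                       sizes = default_sizes()) {
  scenario(
    "s6",
    events = data.frame(
      time = c(t1, t2, t3),
      derived = c("PY", "BF", "MC"),
      ancestral = c("CM", "MC", "CM")
    ),
    sizes = sizes
  )
}

#' @rdname scenario_library
#' @export
scenario_17 <- function(t1 = 2.1e5, t2 = 9.25e5, t3 = 1.5e6,
                        sizes = default_sizes()) {
  scenario(
    "s17",
    events = data.frame(
      time = c(t1, t2, t3),
      derived = c("BF", "MC", "PY"),
      ancestral = c("MC", "PY", "CM")
    ),
    sizes = sizes
  )
}

#' @rdname scenario_library
#' @export
scenario_20 <- function(t1 = 2.1e5, t2 = 9.25e5, t3 = 1.5e6,
                        sizes = default_sizes()) {
  scenario(
    "s20",
    events = data.frame(
      time = c(t1, t2, t3),
      derived = c("BF", "MC", "CM"),
      ancestral = c("MC", "CM", "PY")
    ),
    sizes = sizes
  )
}

#' Replace a scenario's parameters by a prior draw
#' @noRd
scenario_with_params <- function(scn, times, sizes) {
  scn$events$time <- times
  scn$sizes[names(sizes)] <- sizes
  validate_scenario(scn)
  scn
}
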