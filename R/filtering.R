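# Stringent filtering of community checklists and grid-based geographic
# subsampling, mirroring the preprocessing applied to opportunistic
# checklist databases before density modeling.

#' Stringently filter community checklists
#'
#' Retains checklists that are complete, stationary, at personal locations,
#' started within `max_hours_after_dawn` of nautical dawn (and not before
#' it), lasted within `duration_range`, and report a numeric count rather
#' than presence-only "X". The per-rule removal tally applies the rules in
#' the documented order (protocol, location type, time, duration, X,
#' completeness); the retained set is the intersection of the predicates and
#' does not depend on that order.
#'
#' @param checklists checklist data.frame (see [simulate_community_checklists()]
#'   for the column dictionary).
#' @param max_hours_after_dawn latest allowed start, hours after dawn.
#' @param duration_range allowed duration window in minutes.
#' @return list with `checklists` (the retained rows) and `removals`
#'   (named integer vector of rows removed at each rule, in order).
#' @export
filter_checklists <- function(checklists, max_hours_after_dawn = 7,
                              duration_range = c(3, 30)) {
  rules <- list(
    protocol = function(d) d$protocol == "stationary",
    location_type = function(d) d$location_type == "personal",
    time = function(d) d$min_since_dawn >= 0 &
      d$min_since_dawn <= max_hours_after_dawn * 60,
    duration = function(d) d$duration_min >= duration_range[1] &
      d$duration_min <= duration_range[2],
    presence_x = function(d) !d$presence_x & !is.na(d$count),
    completeness = function(d) d$complete
  )
  removals <- setNames(integer(length(rules)), names(rules))
  keep <- rep(TRUE, nrow(checklists))
  for (nm in names(rules)) {
    pass <- rules[[nm]](checklists)
    removals[nm] <- sum(keep & !pass)
    keep <- keep & pass
  }
  list(checklists = checklists[keep, , drop = FALSE], removals = removals)
}

#' Geographic subsampling on a square grid
#'
#' Lays a `grid_m` x `grid_m` grid (half-open cells anchored at the origin)
#' over the checklist locations and keeps exactly one checklist per occupied
#' cell, selected uniformly at random and independently of whether the
#' species was detected. This reduces overrepresentation of popular birding
#' locations.
#'
#' @param checklists checklist data.frame with valid `x_m`, `y_m`.
#' @param grid_m grid cell side (m), default 200.
#' @param seed integer seed.
#' @return the sampled subset of `checklists` (original row order).
#' @export
geographic_sample <- function(checklists, grid_m = 200, seed = 1) {
  assert_scalar_number(grid_m, "grid_m", positive = TRUE)
  if (!nrow(checklists)) return(checklists)
  cell <- paste(floor(checklists$x_m / grid_m),
                floor(checklists$y_m / grid_m))
  keep <- withr::with_seed(as.integer(seed), {
    idx <- seq_len(nrow(checklists))
    picked <- tapply(idx, cell, function(i) i[sample.int(length(i), 1L)])
    sort(unlist(picked, use.names = FALSE))
  })
  checklists[keep, , drop = FALSE]
}
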