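#' Solve a linear assignment problem with birth/death alternatives
#'
#' Minimizes total cost over one-to-one partial matchings of sources (rows)
#' to targets (columns). `NA` or `Inf` entries are forbidden. With
#' `augment = TRUE` (the default) every source may remain unmatched
#' ("death") and every target may remain unmatched ("birth") at
#' `alternative_cost`; by the standard convention this is
#' `alternative_cost_factor` times the maximum feasible cost in the matrix.
#' The optimum is found by a Jonker-Volgenant-style shortest augmenting path
#' search on the augmented square matrix — optimal, not greedy.
#'
#' @param cost Numeric matrix (n sources x m targets); `NA`/`Inf` forbidden.
#' @param alternative_cost Explicit birth/death cost; overrides the factor.
#' @param alternative_cost_factor Multiplier on the maximum feasible cost
#'   used when `alternative_cost` is not given (default 1.05).
#' @param augment If `FALSE`, solve the plain rectangular problem in which
#'   all `min(n, m)` sources/targets must be matched; errors when infeasible.
#' @return A `lap_assignment` list: `matches` (tibble `source`, `target`,
#'   `cost`), `unmatched_sources`, `unmatched_targets`, `total_cost`,
#'   `alternative_cost`.
#' @export
solve_assignment <- function(cost, alternative_cost = NULL,
                             alternative_cost_factor = 1.05,
                             augment = TRUE) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  storage.mode(cost) <- "double"
  cost[is.na(cost)] <- Inf
  n <- nrow(cost); m <- ncol(cost)
  finite <- is.finite(cost)

  if (!augment) {
    if (!any(finite) && n > 0 && m > 0) {
      abort("all assignments are forbidden and no augmentation was requested")
    }
    k <- max(n, m)
    sq <- matrix(0, k, k)
    sq[seq_len(n), seq_len(m)] <- cost
    sol <- hungarian_lap(sq)
    matches <- tibble::tibble(source = seq_len(n),
                              target = sol$match[seq_len(n)]) |>
      dplyr::filter(.data$target <= m)
    matches$cost <- cost[cbind(matches$source, matches$target)]
    if (any(!is.finite(matches$cost))) {
      abort("no feasible complete assignment exists")
    }
    return(new_lap_assignment(matches, n, m, alt = NA_real_))
  }

  if (n == 0L || m == 0L) {
    return(new_lap_assignment(
      tibble::tibble(source = integer(0), target = integer(0),
                     cost = numeric(0)), n, m, alt = 0))
  }
  alt <- alternative_cost %||%
    (if (any(finite)) alternative_cost_factor * max(cost[finite]) else 0)

  # Augmented (n+m) square matrix:
  #   [ C        diag(death) ]
  #   [ diag(birth)  0       ]
  # The zero block lets matched sources/targets pair off their slack rows.
  k <- n + m
  aug <- matrix(Inf, k, k)
  aug[seq_len(n), seq_len(m)] <- cost
  aug[cbind(seq_len(n), m + seq_len(n))] <- alt          # deaths
  aug[cbind(n + seq_len(m), seq_len(m))] <- alt          # births
  aug[n + seq_len(m), m + seq_len(n)] <- 0               # slack block
  sol <- hungarian_lap(aug)

  src_match <- sol$match[seq_len(n)]
  linked <- which(src_match <= m)
  matches <- tibble::tibble(source = linked, target = src_match[linked],
                            cost = cost[cbind(linked, src_match[linked])])
  new_lap_assignment(matches, n, m, alt = alt)
}

new_lap_assignment <- function(matches, n, m, alt) {
  un_s <- setdiff(seq_len(n), matches$source)
  un_t <- setdiff(seq_len(m), matches$target)
  total <- sum(matches$cost) +
    if (is.finite(alt)) alt * (length(un_s) + length(un_t)) else 0
  structure(list(matches = matches,
                 unmatched_sources = un_s,
                 unmatched_targets = un_t,
                 total_cost = total,
                 alternative_cost = alt),
            class = "lap_assignment")
}

#' @export
print.lap_assignment <- function(x, ...) {
  cat(sprintf("<lap_assignment> %d link(s), %d death(s), %d birth(s), total cost %g\n",
              nrow(x$matches), length(x$unmatched_sources),
              length(x$unmatched_targets), x$total_cost))
  invisible(x)
}

# Shortest-augmenting-path Hungarian algorithm on a square matrix `a`
# (entries may be Inf = forbidden). Returns match[i] = column of row i and
# the total cost. O(n^3). Deterministic: ties resolve to the lowest index.
hungarian_lap <- function(a) {
  n <- nrow(a)
  stopifnot(n == ncol(a))
  u <- numeric(n); v <- numeric(n)
  p <- integer(n + 1L)        # p[j + 1] = row currently matched to column j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- a[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      if (!is.finite(delta)) {
        abort("assignment problem is infeasible")
      }
      usedj <- which(used) - 1L
      rows <- p[usedj + 1L]
      u[rows] <- u[rows] + delta
      v[usedj[usedj > 0L]] <- v[usedj[usedj > 0L]] - delta
      minv[!used[-1L]] <- minv[!used[-1L]] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  match[p[-1L]] <- seq_len(n)
  total <- sum(a[cbind(seq_len(n), match)])
  list(match = match, total = total)
}
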