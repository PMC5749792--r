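# Geometric-invariant matching: per-point distance profiles, cross-profile
# Gaussian cost, distinctiveness-ratio acceptance.

#' Build distance profiles for a point set
#'
#' Profile \code{i} is the ascending vector of Euclidean distances from
#' point \code{i} to every other point of the set, in level-0 pixels.
#' Profiles are exactly invariant under rigid motions of the set; with
#' \code{normalize = TRUE} each profile is divided by its own mean, which
#' additionally makes it invariant under isotropic scaling.
#'
#' @param points numeric matrix or data.frame with two columns (x, y);
#'   at least 2 distinct points, no duplicates.
#' @param normalize divide each profile by its mean (default FALSE; the
#'   default matching kernel width is expressed in pixels).
#' @return a \linkS4class{DistanceProfileSet}.
#' @examples
#' distanceProfiles(rbind(c(0, 0), c(3, 0), c(0, 4)))
#' @export
distanceProfiles <- function(points, normalize = FALSE) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points for distance profiles",
                   call. = FALSE)
  D <- as.matrix(stats::dist(pts))
  if (any(D[upper.tri(D)] == 0))
    stop("degenerate geometry: coincident points", call. = FALSE)
  profs <- vector("list", n)
  nf <- numeric(n)
  for (i in seq_len(n)) {
    d <- sort(unname(D[i, -i]))
    nf[i] <- if (normalize) mean(d) else 1
    profs[[i]] <- d / nf[i]
  }
  new("DistanceProfileSet", profiles = profs, normalized = normalize,
      normFactors = nf)
}

#' @rdname DistanceProfileSet-class
#' @param x a \linkS4class{DistanceProfileSet}.
#' @export
profileList <- function(x) x@profiles

setMethod("show", "DistanceProfileSet", function(object) {
  cat(sprintf("DistanceProfileSet: %d profiles of length %d%s\n",
              length(object@profiles),
              if (length(object@profiles)) length(object@profiles[[1]]) else 0L,
              if (object@normalized) " (normalized)" else ""))
})

#' Cross-profile geometric matching cost
#'
#' Similarity between two distance profiles:
#' \deqn{F_{i,j} = \sum_s \sum_t \exp(-(D_i(s) - D_j(t))^2 / \sigma^2)}
#' (\code{mode = "gaussian"}, the default). \code{mode = "as-printed"}
#' flips the exponent sign to the literal published form; it is unbounded,
#' scores larger discrepancies higher and defeats the distinctiveness
#' ratio test, so it exists for audit only.
#'
#' @param profI,profJ numeric distance profiles (vectors), or elements of
#'   [profileList()].
#' @param sigma kernel width, the tolerated distance error (pixels for raw
#'   profiles; default 1).
#' @param mode \code{"gaussian"} or \code{"as-printed"}.
#' @return the scalar cost value.
#' @examples
#' geometricCost(c(1, 2), c(1, 3))  # exp(0)+exp(-4)+exp(-1)+exp(-1)
#' @export
geometricCost <- function(profI, profJ, sigma = 1,
                          mode = c("gaussian", "as-printed")) {
  mode <- match.arg(mode)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  if (!length(profI) || !length(profJ))
    stop("profiles must be non-empty", call. = FALSE)
  sgn <- if (mode == "gaussian") -1 else 1
  sum(exp(sgn * outer(profI, profJ, "-")^2 / sigma^2))
}

# full cost matrix between two profile sets (block-vectorized over one side)
.geometricCostMatrix <- function(profilesA, profilesB, sigma,
                                 mode = "gaussian") {
  pa <- profilesA@profiles; pb <- profilesB@profiles
  m <- length(pa); n <- length(pb)
  allB <- unlist(pb, use.names = FALSE)
  grp <- rep.int(seq_len(n), vapply(pb, length, integer(1)))
  sgn <- if (mode == "gaussian") -1 else 1
  Fm <- matrix(0, m, n)
  for (i in seq_len(m)) {
    E <- exp(sgn * outer(pa[[i]], allB, "-")^2 / sigma^2)
    Fm[i, ] <- vapply(split(colSums(E), grp), sum, numeric(1))
  }
  Fm
}

#' Match point sets by distance-profile similarity
#'
#' For every profile of the first set the candidates of the second set are
#' ranked by the cost of [geometricCost()] descending; the best candidate
#' is accepted only when each of the next \code{K - 1} runner-up
#' similarities is below \code{T} times the best (distinctiveness ratio
#' test). Accepted pairs are additionally made one-to-one, the higher
#' similarity winning conflicts.
#'
#' @param profilesA,profilesB \linkS4class{DistanceProfileSet}s.
#' @param T distinctiveness threshold in \eqn{(0, 1]} (default 0.8).
#' @param K number of ranked candidates examined (>= 2, default 2, the
#'   classic second-best test).
#' @param sigma kernel width passed to the cost (default 1).
#' @param mode kernel mode, see [geometricCost()].
#' @param assignment \code{"ratio"} (default): per-query best candidate,
#'   distinctiveness test, conflicts dropped in favour of the higher
#'   similarity. \code{"greedy"}: greedy global one-to-one assignment on
#'   the full cost matrix (repeatedly take the highest remaining cost and
#'   retire its row and column), so a query losing a conflict falls back
#'   to its next candidate instead of being discarded; the returned
#'   \code{accepted} column marks the pairs the default mode would emit.
#' @return match table with \code{quality = 1 - runnerUp/best} (geometric
#'   distinctiveness) and stage \code{"geometric"}; in greedy mode an
#'   extra logical column \code{accepted}.
#' @export
geometricMatch <- function(profilesA, profilesB, T = 0.8, K = 2L, sigma = 1,
                           mode = c("gaussian", "as-printed"),
                           assignment = c("ratio", "greedy")) {
  mode <- match.arg(mode)
  assignment <- match.arg(assignment)
  if (!is.numeric(T) || length(T) != 1L || T <= 0 || T > 1)
    stop("T must lie in (0, 1]", call. = FALSE)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  m <- length(profilesA@profiles); n <- length(profilesB@profiles)
  if (!m || !n) stop("profile sets must be non-empty", call. = FALSE)
  Fm <- .geometricCostMatrix(profilesA, profilesB, sigma, mode)
  kk <- min(K, n)
  # per-query ranking: best candidate, runner-up ratio, Eq-22 acceptance
  best <- integer(m); ratio <- numeric(m); pass <- logical(m)
  for (i in seq_len(m)) {
    o <- order(Fm[i, ], decreasing = TRUE)
    best[i] <- o[1]
    b <- Fm[i, o[1]]
    if (b <= 0) { ratio[i] <- 1; next }
    if (kk >= 2L) {
      runners <- Fm[i, o[2:kk]]
      ratio[i] <- runners[1] / b
      pass[i] <- all(runners / b < T)
    } else { ratio[i] <- 0; pass[i] <- TRUE }
  }
  if (assignment == "ratio") {
    qi <- which(pass)
    if (!length(qi)) return(emptyMatches())
    ti <- best[qi]; fb <- Fm[cbind(qi, ti)]
    ord <- order(-fb, qi)
    keep <- sort(ord[!duplicated(ti[ord])])
    return(asMatchTable(qi[keep], ti[keep], quality = 1 - ratio[qi][keep],
                        stage = "geometric"))
  }
  # greedy global assignment
  G <- Fm
  qi <- integer(0); ti <- integer(0)
  for (s in seq_len(min(m, n))) {
    top <- arrayInd(which.max(G), dim(G))
    if (G[top] <= 0) break
    qi <- c(qi, top[1]); ti <- c(ti, top[2])
    G[top[1], ] <- -Inf
    G[, top[2]] <- -Inf
  }
  if (!length(qi)) return(emptyMatches())
  o <- order(qi)
  qi <- qi[o]; ti <- ti[o]
  # quality generalizes 1 - runnerUp/best: the row's second-best cost
  # relative to the assigned cost (<= 0 for fallback assignments)
  out <- asMatchTable(qi, ti,
                      quality = 1 - ratio[qi] *
                        Fm[cbind(qi, best[qi])] /
                        pmax(Fm[cbind(qi, ti)], 1e-300),
                      stage = "geometric")
  out$accepted <- pass[qi] & best[qi] == ti
  out
}

#' Write distance profiles to JSON
#'
#' One record per profile: owner index, normalization factor, distances.
#'
#' @param profiles a \linkS4class{DistanceProfileSet}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeProfilesJSON <- function(profiles, path) {
  recs <- lapply(seq_along(profiles@profiles), function(i) {
    list(owner_idx = i, norm_factor = profiles@normFactors[i],
         dists = profiles@profiles[[i]])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
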