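## Compartment-anchored force-directed layout.
##
## Forces per iteration: pairwise inverse-square repulsion between
## instances, Hookean springs on edges toward a rest length, and a
## constant-magnitude pull toward the instance's compartment anchor
## (capped at the remaining distance, so an isolated node settles exactly
## on its anchor). After each step every instance is clamped into its
## compartment zone, which guarantees containment irrespective of force
## equilibrium.

#' Lay out a mixed graph inside its compartment zones
#'
#' Iterative force simulation; deterministic for a given seed. Terminates
#' after `iterations` steps or when the largest per-step displacement
#' falls below `tol`.
#'
#' @param graph A [MixedGraph-class].
#' @param repulsion Repulsion constant (force `repulsion / d^2`).
#' @param spring Spring constant on edges.
#' @param restLength Spring rest length (layout units; the root zone is
#'   100 x 100).
#' @param anchorPull Per-step pull toward the compartment anchor.
#' @param iterations Maximum iterations.
#' @param seed Seed for the initial jitter around the anchors.
#' @param tol Convergence tolerance on the maximum displacement.
#' @return The graph with updated instance `x`/`y`; every instance lies
#'   inside its compartment zone.
#' @export
layoutGraph <- function(graph, repulsion = 30, spring = 0.05, restLength = 5,
                        anchorPull = 0.6, iterations = 250, seed = 1,
                        tol = 1e-3) {
  inst <- graphInstances(graph)
  n <- nrow(inst)
  if (n == 0L) return(graph)
  zones <- graphZones(graph)
  zi <- match(inst$compartment, zones$term_id)
  ax <- zones$anchor_x[zi]; ay <- zones$anchor_y[zi]
  insetX <- 0.02 * (zones$xmax[zi] - zones$xmin[zi])
  insetY <- 0.02 * (zones$ymax[zi] - zones$ymin[zi])
  loX <- zones$xmin[zi] + insetX; hiX <- zones$xmax[zi] - insetX
  loY <- zones$ymin[zi] + insetY; hiY <- zones$ymax[zi] - insetY
  ef <- match(graphEdges(graph)$from, inst$instance_id)
  et <- match(graphEdges(graph)$to, inst$instance_id)
  keepE <- !is.na(ef) & !is.na(et) & ef != et
  ef <- ef[keepE]; et <- et[keepE]
  pos <- withSeed(seed, cbind(ax + runif(n, -1, 1), ay + runif(n, -1, 1)))
  pos[, 1] <- pmin(pmax(pos[, 1], loX), hiX)
  pos[, 2] <- pmin(pmax(pos[, 2], loY), hiY)
  dt <- 0.5
  maxStep <- 2
  for (it in seq_len(iterations)) {
    fx <- numeric(n); fy <- numeric(n)
    if (n > 1L) {
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      d2 <- dx * dx + dy * dy
      d2[d2 < 1e-4] <- 1e-4
      diag(d2) <- Inf
      inv <- repulsion / (d2 * sqrt(d2))
      fx <- rowSums(dx * inv)
      fy <- rowSums(dy * inv)
    }
    if (length(ef)) {
      dx <- pos[et, 1] - pos[ef, 1]
      dy <- pos[et, 2] - pos[ef, 2]
      d <- pmax(sqrt(dx * dx + dy * dy), 1e-3)
      f <- spring * (d - restLength)
      sx <- f * dx / d; sy <- f * dy / d
      for (k in seq_along(ef)) {
        fx[ef[k]] <- fx[ef[k]] + sx[k]; fy[ef[k]] <- fy[ef[k]] + sy[k]
        fx[et[k]] <- fx[et[k]] - sx[k]; fy[et[k]] <- fy[et[k]] - sy[k]
      }
    }
    stepX <- fx * dt; stepY <- fy * dt
    mag <- sqrt(stepX^2 + stepY^2)
    over <- mag > maxStep
    stepX[over] <- stepX[over] * maxStep / mag[over]
    stepY[over] <- stepY[over] * maxStep / mag[over]
    newX <- pos[, 1] + stepX
    newY <- pos[, 2] + stepY
    ## constant anchor pull, capped at the remaining distance
    adx <- ax - newX; ady <- ay - newY
    ad <- sqrt(adx^2 + ady^2)
    pull <- pmin(anchorPull, ad)
    nz <- ad > 0
    newX[nz] <- newX[nz] + pull[nz] * adx[nz] / ad[nz]
    newY[nz] <- newY[nz] + pull[nz] * ady[nz] / ad[nz]
    newX <- pmin(pmax(newX, loX), hiX)
    newY <- pmin(pmax(newY, loY), hiY)
    disp <- max(sqrt((newX - pos[, 1])^2 + (newY - pos[, 2])^2))
    pos[, 1] <- newX; pos[, 2] <- newY
    if (disp < tol) break
  }
  inst$x <- pos[, 1]
  inst$y <- pos[, 2]
  out <- graph
  out@instances <- inst
  out
}
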