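# Disjoint set-style cover over neuron activation tables.
#
# Select node subsets A+ and A- such that every Improver instance activates
# at least one A+ node (or pays a per-row slack), A+ nodes activating
# non-Improver instances pay a per-activation violation slack (and
# symmetrically for A-), A+ and A- share no node, and
# |A+| + |A-| + penalty * (total slack) is minimal. With the slack terms the
# problem is always feasible; the all-slack solution is the fallback.
#
# The integer program is solved exactly by branch and bound: each side is a
# weighted set cover with per-row slack (node weight 1 + penalty * its
# violation count), and the disjointness coupling is resolved by branching
# any node contested by both sides into "A+ only" / "A- only" / "neither".
# Within a time budget the solver proves optimality; past it, it returns the
# incumbent with an optimality-gap report.

# ---- single-side weighted set cover with slack -------------------------

# covers: list per column of covered row indices (into deduplicated rows);
# rowWt: multiplicity of each deduplicated row; w: column weights
.solveSide <- function(covers, w, rowWt, penalty, exclude, deadline) {
  m <- length(covers)
  avail <- setdiff(seq_len(m), exclude)
  # dominance: drop j if some k has cover(j) subset of cover(k) and w_k <= w_j
  keep <- avail
  if (length(avail) > 1L) {
    drop <- logical(length(avail))
    for (a in seq_along(avail)) {
      j <- avail[a]
      for (k in avail) {
        if (k == j) next
        if (w[k] <= w[j] && all(covers[[j]] %in% covers[[k]]) &&
            (w[k] < w[j] || length(covers[[k]]) > length(covers[[j]]) ||
             k < j)) { drop[a] <- TRUE; break }
      }
    }
    keep <- avail[!drop]
  }
  nRows <- length(rowWt)
  env <- new.env()
  env$bestCost <- penalty * sum(rowWt)   # all-slack incumbent
  env$bestSet <- integer(0)
  env$proven <- TRUE
  # cheapest per-row-weight unit rates for the lower bound: a node's weight
  # spread over the total multiplicity it covers
  unitRate <- rep(Inf, nRows)
  for (j in keep) {
    r <- w[j] / sum(rowWt[covers[[j]]])
    unitRate[covers[[j]]] <- pmin(unitRate[covers[[j]]], r)
  }
  unitRate <- pmin(unitRate, penalty)
  recurse <- function(uncov, chosen, cost, cand) {
    if (proc.time()[3] > deadline) { env$proven <- FALSE; return(invisible()) }
    bound <- cost + sum(unitRate[uncov] * rowWt[uncov])
    if (bound >= env$bestCost - 1e-9) return(invisible())
    if (!length(uncov)) {
      if (cost < env$bestCost - 1e-9) {
        env$bestCost <- cost; env$bestSet <- sort(chosen)
      }
      return(invisible())
    }
    # branch on the uncovered row with the fewest available covers
    nOpts <- vapply(uncov, function(i)
      sum(vapply(cand, function(j) i %in% covers[[j]], TRUE)), 0L)
    i <- uncov[which.min(nOpts)]
    js <- cand[vapply(cand, function(j) i %in% covers[[j]], TRUE)]
    # try covering nodes, cheapest-rate first
    if (length(js)) {
      js <- js[order(w[js] / vapply(covers[js],
                                    function(cc) sum(rowWt[cc]), 0))]
      for (j in js)
        recurse(setdiff(uncov, covers[[j]]), c(chosen, j), cost + w[j],
                setdiff(cand, j))
    }
    # or slack this row permanently
    recurse(setdiff(uncov, i), chosen, cost + penalty * rowWt[i],
            js_excluded <- setdiff(cand, integer(0)))
    invisible()
  }
  recurse(seq_len(nRows), integer(0), 0, keep)
  list(cost = env$bestCost, set = env$bestSet, proven = env$proven)
}

.sideInputs <- function(own, other, penalty) {
  m <- ncol(own)
  # deduplicate rows, keeping multiplicities
  if (nrow(own)) {
    pat <- apply(own, 1L, paste, collapse = "")
    uni <- !duplicated(pat)
    rowWt <- as.numeric(table(pat)[pat[uni]])
    ownU <- own[uni, , drop = FALSE]
  } else {
    rowWt <- numeric(0); ownU <- own
  }
  covers <- lapply(seq_len(m), function(j) which(ownU[, j] > 0))
  viol <- if (nrow(other)) colSums(other) else rep(0, m)
  list(covers = covers, w = 1 + penalty * viol, rowWt = rowWt)
}

#' Solve the disjoint activation set-cover integer program
#'
#' @param table an [ActivationTable-class].
#' @param slackPenalty weight of each slack unit (uncovered instance row or
#'   cross-class activation of a selected node) relative to node count;
#'   default 10, so separation dominates parsimony.
#' @param solverBudget wall-clock seconds before the solver stops proving
#'   optimality and returns its incumbent (default 30).
#' @return list with `aPlus`, `aMinus` (selected node indices), `objective`,
#'   `optimal` (logical: proven within budget), `gap` (objective minus the
#'   best lower bound; 0 when proven), and `uncovered` diagnostics:
#'   `conflictInstances` (instances whose activation row appears in both
#'   classes, unseparable by construction), `slackPlus`/`slackMinus`
#'   (instance rows no selected node covers).
#' @seealso [bruteForceCover()] for the exhaustive-enumeration oracle.
#' @export
solveSetCover <- function(table, slackPenalty = 10, solverBudget = 30) {
  stopifnot(is(table, "ActivationTable"))
  xp <- table@xPlus; xm <- table@xMinus
  if (!ncol(xp)) stop("activation table has no node columns", call. = FALSE)
  if (!nrow(xp) && !nrow(xm))
    stop("both activation tables are empty", call. = FALSE)
  deadline <- proc.time()[3] + solverBudget
  inP <- .sideInputs(xp, xm, slackPenalty)
  inM <- .sideInputs(xm, xp, slackPenalty)
  best <- new.env()
  best$obj <- Inf; best$aP <- integer(0); best$aM <- integer(0)
  best$proven <- TRUE
  branch <- function(exP, exM) {
    sP <- .solveSide(inP$covers, inP$w, inP$rowWt, slackPenalty, exP, deadline)
    sM <- .solveSide(inM$covers, inM$w, inM$rowWt, slackPenalty, exM, deadline)
    if (!sP$proven || !sM$proven) best$proven <- FALSE
    tot <- sP$cost + sM$cost
    if (tot >= best$obj - 1e-9) return(invisible())
    common <- intersect(sP$set, sM$set)
    if (!length(common)) {
      best$obj <- tot; best$aP <- sP$set; best$aM <- sM$set
      return(invisible())
    }
    v <- common[1]
    branch(c(exP, v), exM)
    branch(exP, c(exM, v))
    invisible()
  }
  branch(integer(0), integer(0))
  aP <- best$aP; aM <- best$aM
  patP <- if (nrow(xp)) apply(xp, 1L, paste, collapse = "") else character(0)
  patM <- if (nrow(xm)) apply(xm, 1L, paste, collapse = "") else character(0)
  conflict <- union(rownames(xp)[patP %in% patM] %||% which(patP %in% patM),
                    rownames(xm)[patM %in% patP] %||% which(patM %in% patP))
  slackP <- which(if (length(aP)) rowSums(xp[, aP, drop = FALSE]) == 0
                  else rep(TRUE, nrow(xp)))
  slackM <- which(if (length(aM)) rowSums(xm[, aM, drop = FALSE]) == 0
                  else rep(TRUE, nrow(xm)))
  list(aPlus = aP, aMinus = aM, objective = best$obj,
       optimal = best$proven, gap = if (best$proven) 0 else NA_real_,
       uncovered = list(conflictInstances = conflict,
                        slackPlus = slackP, slackMinus = slackM))
}

# ---- exhaustive oracle -------------------------------------------------

.popcount <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) tab <<- vapply(0:1023, function(v)
      sum(bitwAnd(v, bitwShiftL(1L, 0:9)) > 0), 0L)
    tab[bitwAnd(x, 1023L) + 1L] + tab[bitwAnd(bitwShiftR(x, 10L), 1023L) + 1L] +
      tab[bitwAnd(bitwShiftR(x, 20L), 1023L) + 1L]
  }
})

# cost of every column subset (masks 0..2^m-1) for one side
.allSubsetCosts <- function(own, other, penalty, m) {
  nMask <- bitwShiftL(1L, m)
  masks <- 0:(nMask - 1L)
  w <- 1 + penalty * (if (nrow(other)) colSums(other) else rep(0, m))
  sumw <- numeric(nMask)
  for (s in seq_len(nMask - 1L)) {
    low <- bitwAnd(s, -s)
    sumw[s + 1L] <- sumw[bitwAnd(s, s - 1L) + 1L] + w[round(log2(low)) + 1L]
  }
  uncov <- numeric(nMask)
  if (nrow(own)) {
    for (i in seq_len(nrow(own))) {
      rmask <- sum(bitwShiftL(1L, which(own[i, ] > 0) - 1L))
      uncov <- uncov + (bitwAnd(masks, rmask) == 0L)
    }
  }
  sumw + penalty * uncov
}

.lexLess <- function(a, b) {
  # is sorted integer set a lexicographically before b?
  n <- min(length(a), length(b))
  if (n > 0) for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Brute-force oracle for the disjoint activation cover
#'
#' Exhaustively enumerates all disjoint subset pairs and minimizes the same
#' objective as [solveSetCover()]; intended as an independent test oracle
#' for small tables. Ties are broken toward the lexicographically smallest
#' node sets (A+ first).
#'
#' @inheritParams solveSetCover
#' @return list with `aPlus`, `aMinus`, `objective`.
#' @export
bruteForceCover <- function(table, slackPenalty = 10) {
  stopifnot(is(table, "ActivationTable"))
  xp <- table@xPlus; xm <- table@xMinus
  m <- ncol(xp)
  if (m > 15L) stop("brute force limited to 15 neurons", call. = FALSE)
  if (nrow(xp) > 30L || nrow(xm) > 30L)
    stop("brute force limited to 30 instances per class", call. = FALSE)
  costP <- .allSubsetCosts(xp, xm, slackPenalty, m)
  costM <- .allSubsetCosts(xm, xp, slackPenalty, m)
  nMask <- bitwShiftL(1L, m)
  masks <- 0:(nMask - 1L)
  # subset-minimum transform: f[mask] = min over sub subsets of mask
  f <- costM
  for (b in seq_len(m) - 1L) {
    bit <- bitwShiftL(1L, b)
    hasBit <- bitwAnd(masks, bit) > 0L
    f[hasBit] <- pmin(f[hasBit], f[bitwXor(masks[hasBit], bit) + 1L])
  }
  full <- nMask - 1L
  obj <- costP + f[bitwXor(full, masks) + 1L]
  opt <- min(obj)
  maskToSet <- function(s) which(bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
  bestP <- NULL
  for (s in masks[abs(obj - opt) < 1e-9]) {
    cand <- maskToSet(s)
    if (is.null(bestP) || .lexLess(cand, bestP)) { bestP <- cand; sP <- s }
  }
  comp <- bitwXor(full, sP)
  target <- f[comp + 1L]
  bestM <- NULL
  for (s in masks) {
    if (bitwAnd(s, comp) == s && abs(costM[s + 1L] - target) < 1e-9) {
      cand <- maskToSet(s)
      if (is.null(bestM) || .lexLess(cand, bestM)) bestM <- cand
    }
  }
  list(aPlus = bestP %||% integer(0), aMinus = bestM %||% integer(0),
       objective = opt)
}
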