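#' Specification of a synthetic two-group cohort
#'
#' Describes the generative model the analysis assumes: independent
#' non-negative count variables (Poisson, or negative binomial when a
#' dispersion is supplied) and rare binary phenomena (Bernoulli), each with
#' group-specific parameters, over two diagnostic groups of configurable
#' size. Variables whose group parameters differ by at least the stated
#' effect floors are recorded as the planted discriminative set, the ground
#' truth for structure-recovery experiments.
#'
#' @param variables data.frame with columns `name`, `family` (`"count"` or
#'   `"binary"`), `parAD`, `parINPH` (means for counts, probabilities for
#'   binaries) and optionally `dispersion` (NA = Poisson; otherwise negative
#'   binomial `size` parameter).
#' @param nAD,nINPH group sizes, >= 1.
#' @param planted character vector of planted variable names (subset of
#'   `variables$name`); computed by [specFromCohort()] when calibrating from
#'   data.
#' @return a validated `cohortSpec` list.
#' @export
cohortSpec <- function(variables, nAD = 8L, nINPH = 11L, planted = character()) {
  stopifnot(is.data.frame(variables),
            all(c("name", "family", "parAD", "parINPH") %in% names(variables)),
            nAD >= 1, nINPH >= 1)
  if (!"dispersion" %in% names(variables)) variables$dispersion <- NA_real_
  if (anyDuplicated(variables$name)) stop("duplicate variable names")
  if (!all(variables$family %in% c("count", "binary")))
    stop("family must be 'count' or 'binary'")
  bin <- variables$family == "binary"
  pr <- c(variables$parAD[bin], variables$parINPH[bin])
  if (length(pr) && (any(pr < 0) || any(pr > 1)))
    stop("binary probabilities must lie in [0, 1]")
  if (any(variables$parAD[!bin] < 0) || any(variables$parINPH[!bin] < 0))
    stop("count means must be non-negative")
  if (!all(planted %in% variables$name))
    stop("planted variables must be declared variables")
  structure(list(variables = variables, nAD = as.integer(nAD),
                 nINPH = as.integer(nINPH), planted = planted),
            class = "cohortSpec")
}

#' Calibrate a synthetic spec from an observed cohort
#'
#' Variables whose observed maximum is at most 1 are treated as binary with
#' group-wise frequencies; the rest are counts with group-wise sample means
#' (Poisson family). Variables whose group means differ by at least
#' `countEffectFloor` responses (counts) or `probEffectFloor` (binaries) are
#' recorded as planted.
#'
#' @param x a [RorschachCohort-class] with both groups present.
#' @param countEffectFloor,probEffectFloor effect floors for the planted set.
#' @return a [cohortSpec()] list.
#' @examples
#' sp <- specFromCohort(rorschachFixture())
#' "A" %in% sp$planted
#' @export
specFromCohort <- function(x, countEffectFloor = 1.0, probEffectFloor = 0.3) {
  g <- as.character(cohortGroups(x))
  if (length(unique(g)) < 2L) stop("both groups must be present")
  m <- cohortCounts(x)
  mAD <- colMeans(m[g == "AD", , drop = FALSE])
  mIN <- colMeans(m[g == "INPH", , drop = FALSE])
  fam <- ifelse(apply(m, 2, max) <= 1, "binary", "count")
  vars <- data.frame(name = colnames(m), family = fam,
                     parAD = mAD, parINPH = mIN,
                     dispersion = NA_real_,
                     row.names = NULL, stringsAsFactors = FALSE)
  floorBy <- ifelse(fam == "binary", probEffectFloor, countEffectFloor)
  planted <- vars$name[abs(mAD - mIN) >= floorBy]
  cohortSpec(vars, nAD = sum(g == "AD"), nINPH = sum(g == "INPH"),
             planted = planted)
}

#' Sample a synthetic cohort
#'
#' Draws an independent cohort under the spec's generative model:
#' `Poisson(mu_g)` (or negative binomial for variables with a dispersion)
#' for counts and `Bernoulli(p_g)` for binaries. The result has exactly the
#' schema of a loaded cohort and passes the same validation and scaling.
#'
#' @param spec a [cohortSpec()] list.
#' @param seed integer seed; the same seed reproduces the same cohort.
#' @return a [RorschachCohort-class] with `nAD + nINPH` subjects.
#' @export
sampleCohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohortSpec"))
  v <- spec$variables
  n <- spec$nAD + spec$nINPH
  grp <- rep(c("AD", "INPH"), c(spec$nAD, spec$nINPH))
  .withSeed(seed, {
    cols <- lapply(seq_len(nrow(v)), function(k) {
      par <- ifelse(grp == "AD", v$parAD[k], v$parINPH[k])
      if (v$family[k] == "binary") {
        rbinom(n, 1L, par)
      } else if (is.na(v$dispersion[k])) {
        rpois(n, par)
      } else {
        rnbinom(n, size = v$dispersion[k], mu = par)
      }
    })
    m <- do.call(cbind, cols)
    colnames(m) <- v$name
    rownames(m) <- paste(grp, stats::ave(seq_len(n), grp, FUN = seq_along))
    RorschachCohort(m, group = grp)
  })
}

#' Quantify recovery of planted structure by the full pipeline
#'
#' For each of `nRuns` seeded replicates: sample a cohort, scale it, embed
#' it in 2-D and record the minimum linear misplacement; append the group
#' indicators, rescale, train the contractive map, extract the minimum
#' spanning tree, and record -- for every planted variable -- whether it is
#' tree-adjacent to the indicator of the group in which its parameter is
#' larger.
#'
#' @param spec a [cohortSpec()] with at least one planted variable (the
#'   adjacency fractions are empty, but misplacement is still measured, for
#'   a spec without planted variables).
#' @param nRuns number of replicates, >= 1.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param autocmConfig,mdsMetric pipeline stage settings.
#' @param stages character subset of `c("separation", "graph")` to evaluate.
#' @return list with `adjacency` (named fraction per planted variable),
#'   `misplaced` (integer vector, one per run), and `paramError` (mean
#'   absolute difference between per-group sample means and the generating
#'   parameters).
#' @export
recoveryEval <- function(spec, nRuns = 50L, seed = 1L,
                         autocmConfig = autoCMConfig(),
                         mdsMetric = "manhattan",
                         stages = c("separation", "graph")) {
  stopifnot(inherits(spec, "cohortSpec"), nRuns >= 1)
  stages <- match.arg(stages, several.ok = TRUE)
  planted <- spec$planted
  adj <- matrix(NA, nRuns, length(planted),
                dimnames = list(NULL, planted))
  mis <- rep(NA_integer_, nRuns)
  perr <- numeric(nRuns)
  v <- spec$variables
  target <- ifelse(v$parINPH >= v$parAD, "INPH", "DEMENZA")
  names(target) <- v$name
  for (r in seq_len(nRuns)) {
    co <- sampleCohort(spec, seed = seed + r)
    g <- as.character(cohortGroups(co))
    m <- cohortCounts(co)
    est <- rbind(colMeans(m[g == "AD", , drop = FALSE]),
                 colMeans(m[g == "INPH", , drop = FALSE]))
    perr[r] <- mean(abs(est - rbind(v$parAD, v$parINPH)))
    if ("separation" %in% stages) {
      sco <- scaleCohort(co)
      emb <- projectCohort(sco, metric = mdsMetric)
      mis[r] <- linearSeparation(emb, g)@misplacedCount
    }
    if ("graph" %in% stages && length(planted)) {
      aug <- scaleCohort(appendGroupIndicators(co))
      cfg <- autocmConfig
      cfg$seed <- .stageSeed(seed + r, "autocm")
      fit <- suppressWarnings(trainAutoCM(aug, cfg))
      tree <- minimumSpanningTree(associationMatrix(fit))
      e <- graphEdges(tree)
      for (p in planted) {
        adj[r, p] <- any((e$u == p & e$v == target[[p]]) |
                         (e$v == p & e$u == target[[p]]))
      }
    }
  }
  list(adjacency = if (length(planted)) colMeans(adj) else
         stats::setNames(numeric(0), character(0)),
       misplaced = mis,
       paramError = mean(perr))
}
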