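#' @rdname accessors
#' @export
setMethod("subjectIds", "RorschachCohort", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("cohortGroups", "RorschachCohort",
          function(x) SummarizedExperiment::colData(x)$group)

#' @rdname accessors
#' @export
setMethod("variableNames", "RorschachCohort", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("cohortCounts", "RorschachCohort",
          function(x) t(SummarizedExperiment::assay(x, "counts")))

#' @rdname accessors
#' @export
setMethod("scaledMatrix", "RorschachCohort", function(x) {
  if (!"scaled" %in% SummarizedExperiment::assayNames(x))
    stop("no 'scaled' assay; run scaleCohort() first")
  t(SummarizedExperiment::assay(x, "scaled"))
})

setMethod("show", "RorschachCohort", function(object) {
  g <- table(cohortGroups(object))
  cat(sprintf("RorschachCohort: %d subjects (%s) x %d variables\n",
              ncol(object),
              paste(sprintf("%d %s", g, names(g)), collapse = ", "),
              nrow(object)))
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
})

#' Read a cohort of coded protocols from CSV
#'
#' The expected layout is a comma-separated UTF-8 file with a header row and
#' columns `subject_id`, `group`, followed by one column per coding variable
#' (response counts or 0/1 phenomenon flags). Missing trailing cells -- as
#' occur when the last columns of a printed row are cut off -- are filled
#' with 0 and reported with a warning; any other non-integer or negative cell
#' is an error naming the offending row and column.
#'
#' @param path path to a CSV file.
#' @return a [RorschachCohort-class].
#' @examples
#' co <- rorschachFixture()
#' co
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  df <- tryCatch(
    read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse cohort file: ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("cohort file has no data rows: ", path)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("cohort file must have 'subject_id' and 'group' columns")
  vars <- setdiff(names(df), need)
  if (length(vars) == 0L) stop("cohort file has no variable columns")
  m <- as.matrix(df[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$subject_id
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    # trailing holes only: every NA must extend to the final column of its row
    trailing <- vapply(seq_len(nrow(holes)), function(k) {
      r <- holes[k, 1]
      all(is.na(m[r, seq(holes[k, 2], ncol(m))]))
    }, logical(1))
    if (!all(trailing)) {
      bad <- holes[!trailing, , drop = FALSE][1, ]
      stop(sprintf("missing value at subject '%s', variable '%s'",
                   rownames(m)[bad[1]], colnames(m)[bad[2]]))
    }
    warning(sprintf(
      "filled %d missing trailing cell(s) with 0 (subjects: %s)",
      nrow(holes), paste(unique(rownames(m)[holes[, 1]]), collapse = ", ")))
    m[is.na(m)] <- 0
  }
  bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative value at subject '%s', variable '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  RorschachCohort(m, group = df$group)
}

#' Write a cohort back to the standard CSV layout
#'
#' Inverse of [readCohort()]: `readCohort(writeCohort(x, f))` reproduces the
#' table cell for cell.
#'
#' @param x a [RorschachCohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(x, path) {
  df <- data.frame(subject_id = subjectIds(x),
                   group = as.character(cohortGroups(x)),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(cohortCounts(x), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled 19-subject reference cohort
#'
#' Loads the packaged cohort of 19 coded protocols (8 AD, 11 INPH, 45
#' variables) used throughout the documentation and the reproduction tests.
#'
#' @return a [RorschachCohort-class] with 19 subjects and 45 variables.
#' @export
rorschachFixture <- function() {
  readCohort(system.file("extdata", "rorschach_cohort.csv",
                         package = "RorschachMap", mustWork = TRUE))
}

#' Dictionary from descriptive (English) variable names to table headers
#'
#' The descriptive-statistics table of the source cohort labels variables in
#' English while the per-subject table uses the Italian scoring shorthand;
#' this named vector maps the former to the latter (e.g. `Popular` -> `BAN`,
#' `Refuse` -> `Rifiuti`).
#'
#' @return named character vector; names are descriptive labels, values the
#'   cohort column names.
#' @export
variableDictionary <- function() {
  c("Number of answers" = "Numero Risposte",
    "Global (G)" = "G", "Details (D)" = "D", "Little details (Dd)" = "Dd",
    "Details to global (DG)" = "DG",
    "F (shape)" = "F", "F+ (positive shape)" = "F+",
    "F- (negative shape)" = "F-",
    "M (human kinesthetic activity)" = "M",
    "FM (animal kinesthetic activity)" = "FM",
    "m (inanimate movement)" = "m", "CF (color)" = "CF",
    "FCho (diffuse shading)" = "Fcho", "Cho (pure shading)" = "CHO",
    "Popular" = "BAN", "Original" = "ORIG", "Original good form" = "ORIG+",
    "A (animals)" = "A", "Ad (animal details)" = "Ad",
    "H (human)" = "U", "(h) (fantastic human)" = "(u)",
    "Hd (human details)" = "Ud",
    "Obj (object)" = "Obj", "Food" = "Cibo", "Nature" = "Nat",
    "Botanic" = "Bot", "Anatomical" = "Anat", "Smoke" = "Fumo",
    "Cartoon" = "Cartoon", "Art" = "Art",
    "IR (reality index)" = "IR",
    "TRI I (Erlebnistypus I)" = "TRI I", "TRI II (Erlebnistypus II)" = "TRI II",
    "Perseveration" = "Perseverazioni", "Inadequacy" = "Inadeguatezza",
    "Insecurity" = "Insicurezza", "Stereotyped" = "Stereotipie",
    "Refuse" = "Rifiuti", "Confabulation" = "Confabulazione",
    "Abstraction" = "Astrazione", "Contamination" = "Contaminazione",
    "Difficulty of naming" = "Diff. Denominazione",
    "Self-reference" = "Autoriferimento",
    "Devitalization" = "Devitalizzazione", "Sensation" = "Sensazione")
}

# rule definitions: each rule equates a total column with a sum of parts
.protocolRules <- function() {
  list(
    L   = list(total = "Numero Risposte", parts = c("G", "D", "Dd", "DG")),
    Det = list(total = "Numero Risposte",
               parts = c("F", "M", "FM", "m", "CF", "Fcho", "CHO")),
    F   = list(total = "F", parts = c("F+", "F-"))
  )
}

#' Check structural sum rules of the coding scheme
#'
#' Three structural identities of the coding scheme are checked per subject:
#' the localization codes (G, D, Dd, DG) must sum to the response count, the
#' determinant codes (F, M, FM, m, CF, Fcho, CHO) must sum to the response
#' count, and F must equal F+ plus F-. Violations are reported, never fatal:
#' real protocols occasionally carry transcription slips, and downstream
#' stages are robust to them.
#'
#' @param x a [RorschachCohort-class] containing the variables the rules
#'   refer to (a missing rule variable is a configuration error).
#' @return a [ProtocolValidation-class]; its violation table is empty iff all
#'   rules hold for all subjects.
#' @examples
#' validateProtocol(rorschachFixture())
#' @export
validateProtocol <- function(x) {
  m <- cohortCounts(x)
  rules <- .protocolRules()
  allvars <- unique(unlist(lapply(rules, function(r) c(r$total, r$parts))))
  missing <- setdiff(allvars, colnames(m))
  if (length(missing))
    stop("rule variables absent from cohort: ", paste(missing, collapse = ", "))
  out <- lapply(names(rules), function(rn) {
    r <- rules[[rn]]
    expd <- m[, r$total]
    obsd <- rowSums(m[, r$parts, drop = FALSE])
    bad <- which(expd != obsd)
    if (!length(bad)) return(NULL)
    data.frame(subject_id = rownames(m)[bad], rule = rn,
               expected = as.integer(expd[bad]),
               observed = as.integer(obsd[bad]),
               stringsAsFactors = FALSE)
  })
  viol <- do.call(rbind, out)
  if (is.null(viol))
    viol <- data.frame(subject_id = character(), rule = character(),
                       expected = integer(), observed = integer(),
                       stringsAsFactors = FALSE)
  viol <- viol[order(viol$rule, viol$subject_id), , drop = FALSE]
  rownames(viol) <- NULL
  counts <- vapply(names(rules), function(rn) sum(viol$rule == rn), integer(1))
  methods::new("ProtocolValidation", violations = viol, ruleCounts = counts)
}

#' @rdname accessors
#' @export
setMethod("violationTable", "ProtocolValidation", function(x) x@violations)

setMethod("show", "ProtocolValidation", function(object) {
  cat("ProtocolValidation:", nrow(object@violations), "violation(s)\n")
  for (rn in names(object@ruleCounts))
    cat(sprintf("  rule %-4s %d subject(s)\n", rn, object@ruleCounts[[rn]]))
  if (nrow(object@violations)) print(object@violations)
})

#' Per-variable descriptive statistics
#'
#' Mean, standard deviation, minimum and maximum of every coding variable,
#' in cohort column order. The default standard deviation uses the sample
#' (n - 1) convention, which is the convention the reference cohort's printed
#' statistics follow.
#'
#' @param x a [RorschachCohort-class].
#' @param sdType `"sample"` (n - 1, default) or `"population"` (n).
#' @return data.frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @examples
#' head(describeCohort(rorschachFixture()))
#' @export
describeCohort <- function(x, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  m <- cohortCounts(x)
  if (nrow(m) == 0L) stop("empty cohort")
  n <- nrow(m)
  sds <- apply(m, 2, sd)
  if (sdType == "population") sds <- sds * sqrt((n - 1) / n)
  if (n == 1L) sds[] <- 0
  data.frame(variable = colnames(m),
             mean = colMeans(m), sd = sds,
             min = apply(m, 2, min), max = apply(m, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Min-max scale the cohort to the unit interval
#'
#' Applies the per-variable affine map (x - min) / (max - min), the input
#' range expected by the contractive map and the other unsupervised stages.
#' Constant variables are mapped to 0 everywhere so that they stay inert
#' downstream. The per-variable ranges are stored in `rowData` for exact
#' inversion via [inverseScale()].
#'
#' @param x a [RorschachCohort-class] with at least 2 subjects.
#' @return `x` with an additional `"scaled"` assay.
#' @export
scaleCohort <- function(x) {
  m <- SummarizedExperiment::assay(x, "counts")  # variables x subjects
  if (ncol(m) < 2L) stop("scaling needs at least 2 subjects")
  mins <- apply(m, 1, min)
  maxs <- apply(m, 1, max)
  rng <- maxs - mins
  sc <- (m - mins) / ifelse(rng == 0, 1, rng)
  sc[rng == 0, ] <- 0
  SummarizedExperiment::assay(x, "scaled") <- sc
  SummarizedExperiment::rowData(x)$scaleMin <- mins
  SummarizedExperiment::rowData(x)$scaleMax <- maxs
  methods::validObject(x)
  x
}

#' Invert the min-max scaling
#'
#' Maps a scaled subjects x variables matrix back to the original count
#' scale using the ranges stored by [scaleCohort()]. For non-constant
#' variables this recovers the integers exactly (up to rounding noise);
#' constant variables return their constant value.
#'
#' @param x a [RorschachCohort-class] that has been through [scaleCohort()].
#' @param scaled subjects x variables matrix in \[0, 1\]; defaults to the
#'   cohort's own scaled assay.
#' @return subjects x variables numeric matrix on the original scale.
#' @export
inverseScale <- function(x, scaled = scaledMatrix(x)) {
  rd <- SummarizedExperiment::rowData(x)
  if (!all(c("scaleMin", "scaleMax") %in% names(rd)))
    stop("no stored scaling ranges; run scaleCohort() first")
  mins <- rd$scaleMin[match(colnames(scaled), rownames(x))]
  maxs <- rd$scaleMax[match(colnames(scaled), rownames(x))]
  sweep(sweep(scaled, 2, maxs - mins, "*"), 2, mins, "+")
}

#' Append the two pathology-indicator variables
#'
#' Adds binary `INPH` and `DEMENZA` columns (1 for members of the INPH and
#' AD groups respectively) after the last coding variable, producing the
#' augmented variable set on which the contractive map learns the
#' relationship between each variable and the two diagnoses.
#'
#' @param x a [RorschachCohort-class] with both groups present and without
#'   existing indicator columns.
#' @return a new [RorschachCohort-class] with two extra variables (the
#'   scaled assay, if any, is dropped; rescale after appending).
#' @examples
#' ncol(cohortCounts(appendGroupIndicators(rorschachFixture())))
#' @export
appendGroupIndicators <- function(x) {
  g <- cohortGroups(x)
  if (length(unique(as.character(g))) < 2L)
    stop("both groups must be present to append indicators")
  if (any(c("INPH", "DEMENZA") %in% variableNames(x)))
    stop("indicator variables already present")
  m <- cbind(cohortCounts(x),
             INPH = as.integer(g == "INPH"),
             DEMENZA = as.integer(g == "AD"))
  RorschachCohort(m, group = g)
}
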