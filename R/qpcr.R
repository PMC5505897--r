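# Comparative-Ct (2^-ddCt) relative quantification of real-time PCR
# plates with an endogenous control gene (e.g. beta-actin) and a
# calibrator diet group.

#' Construct a QpcrPlate
#'
#' @param data data.frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct` (one row per technical replicate).
#' @param targetGene,controlGene labels of the target and of the
#'   endogenous-control gene; every sample needs at least one replicate of
#'   each.
#' @return A [QpcrPlate-class].
#' @export
QpcrPlate <- function(data, targetGene, controlGene) {
  new("QpcrPlate", data = as.data.frame(data), targetGene = targetGene,
      controlGene = controlGene)
}

setMethod("show", "QpcrPlate", function(object) {
  d <- object@data
  cat(sprintf(
    "QpcrPlate: %d samples, target '%s', control '%s', %d Ct values\n",
    length(unique(d$sample)), object@targetGene, object@controlGene,
    nrow(d)))
})

#' Read / write a qPCR plate as long-format TSV
#'
#' Columns: `sample`, `group`, `gene`, `replicate`, `ct`.
#'
#' @param file TSV path.
#' @param targetGene,controlGene gene labels (see [QpcrPlate()]).
#' @return `readQpcrPlate` returns a [QpcrPlate-class]; `writeQpcrPlate`
#'   invisibly returns the path.
#' @importFrom utils read.delim write.table
#' @export
readQpcrPlate <- function(file, targetGene, controlGene) {
  QpcrPlate(read.delim(file), targetGene, controlGene)
}

#' @rdname readQpcrPlate
#' @param plate a [QpcrPlate-class].
#' @export
writeQpcrPlate <- function(plate, file) {
  write.table(plate@data, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Comparative-Ct relative expression (2^-ddCt)
#'
#' Technical replicates are averaged arithmetically per sample and gene.
#' Per sample, `dct = mean target Ct - mean control Ct`; `ddct = dct -
#' mean dct of the calibrator group`; relative quantity `rq = 2^(-ddct)`.
#' By construction the geometric mean of the calibrator group's `rq` is 1.
#'
#' @param plate a [QpcrPlate-class].
#' @param calibratorGroup group used as calibrator (default `"AL"`; must
#'   be present in the plate).
#' @return A data.frame with one row per sample: `sample`, `group`,
#'   `meanTargetCt`, `meanControlCt`, `dct`, `ddct`, `rq`.
#' @examples
#' plate <- simulateQpcr(QpcrScenario(log2Offsets = c(0, 1, 3),
#'                                    ctNoiseSd = 0, seed = 8))
#' aggregate(rq ~ group, ddct(plate), mean)
#' @export
ddct <- function(plate, calibratorGroup = "AL") {
  stopifnot(is(plate, "QpcrPlate"))
  validObject(plate)
  d <- plate@data
  if (!calibratorGroup %in% d$group) {
    stop("calibrator group '", calibratorGroup, "' absent from plate",
         call. = FALSE)
  }
  tg <- d[d$gene == plate@targetGene, ]
  cg <- d[d$gene == plate@controlGene, ]
  if (!nrow(cg)) stop("control gene missing", call. = FALSE)
  tMean <- tapply(tg$ct, tg$sample, mean)
  cMean <- tapply(cg$ct, cg$sample, mean)
  samples <- unique(d[, c("sample", "group")])
  samples <- samples[order(match(samples$sample, names(tMean))), ]
  out <- data.frame(sample = samples$sample, group = samples$group,
                    meanTargetCt = as.numeric(tMean[samples$sample]),
                    meanControlCt = as.numeric(cMean[samples$sample]))
  out$dct <- out$meanTargetCt - out$meanControlCt
  calMean <- mean(out$dct[out$group == calibratorGroup])
  out$ddct <- out$dct - calMean
  out$rq <- 2^(-out$ddct)
  out
}

#' Group comparison of relative expression
#'
#' One-way ANOVA with Tukey HSD on the per-sample relative expression,
#' mirroring the per-gene qPCR analysis of the study. The response is the
#' relative quantity `rq` by default; `response = "dct"` tests the
#' delta-Ct values instead (the two orderings agree, the scales differ).
#'
#' @param rel result of [ddct()].
#' @param response `"rq"` (default) or `"dct"`.
#' @return A list with `anova` (from [anovaOneway()]) and `tukey` (from
#'   [tukeyHsd()]).
#' @export
testRelExpression <- function(rel, response = c("rq", "dct")) {
  response <- match.arg(response)
  list(anova = anovaOneway(rel[[response]], rel$group),
       tukey = tukeyHsd(rel[[response]], rel$group),
       response = response)
}
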