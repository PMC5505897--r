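#' Construct an AmpliconSpec with automatic cytosine annotation
#'
#' Scans the reference for cytosines and annotates each as `CG` (next base
#' is G) or `CH` (next base is A, C or T, or the cytosine is the terminal
#' base). Every cytosine in the reference becomes a site: BSAS reports
#' methylation in both contexts.
#'
#' @param seq reference sequence: a character string or
#'   [Biostrings::DNAString] of uppercase A/C/G/T.
#' @param name amplicon label.
#' @param annotations optional named [IRanges::IRanges] of amplicon-local
#'   annotation intervals (e.g. a consensus-motif span).
#' @return An [AmpliconSpec-class].
#' @examples
#' amp <- AmpliconSpec("ACGTTACCGA", name = "toy")
#' ampliconSites(amp)
#' @importFrom Biostrings DNAString
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges
#' @export
AmpliconSpec <- function(seq, name = "amplicon", annotations = IRanges()) {
  seq <- DNAString(as.character(seq))
  chars <- strsplit(as.character(seq), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("reference must contain only A/C/G/T", call. = FALSE)
  }
  cpos <- which(chars == "C")                  # 1-based
  nxt <- chars[cpos + 1L]                      # NA at terminal base
  ctx <- as.character(ifelse(!is.na(nxt) & nxt == "G", "CG", "CH"))
  sites <- DataFrame(offset = as.integer(cpos - 1L), context = ctx)
  new("AmpliconSpec", name = name, seq = seq, sites = sites,
      annotations = annotations)
}

#' Site annotation of an amplicon
#'
#' @param x an [AmpliconSpec-class].
#' @param context optional filter, `"CG"` or `"CH"`.
#' @return [S4Vectors::DataFrame] with `offset` (0-based) and `context`.
#' @export
setGeneric("ampliconSites", function(x, context = NULL) {
  standardGeneric("ampliconSites")
})

#' @rdname ampliconSites
#' @export
setMethod("ampliconSites", "AmpliconSpec", function(x, context = NULL) {
  st <- x@sites
  if (!is.null(context)) {
    context <- match.arg(context, c("CG", "CH"))
    st <- st[st$context == context, , drop = FALSE]
  }
  st
})

#' Reference sequence of an amplicon
#' @param x an [AmpliconSpec-class].
#' @return A [Biostrings::DNAString].
#' @export
setGeneric("ampliconSeq", function(x) standardGeneric("ampliconSeq"))

#' @rdname ampliconSeq
#' @export
setMethod("ampliconSeq", "AmpliconSpec", function(x) x@seq)

setMethod("show", "AmpliconSpec", function(object) {
  st <- object@sites
  cat(sprintf("AmpliconSpec '%s': %d bp, %d CG sites, %d CH sites\n",
              object@name, length(object@seq),
              sum(st$context == "CG"), sum(st$context == "CH")))
  if (length(object@annotations)) {
    cat("  annotations:", paste(names(object@annotations), collapse = ", "),
        "\n")
  }
})

#' Generate a random amplicon with CG sites planted at given offsets
#'
#' Builds a random reference of the requested length carrying a CG
#' dinucleotide at each requested 0-based offset and no CG anywhere else;
#' all remaining cytosines are therefore CH sites. This reproduces the
#' layouts of the promoter amplicons studied by BSAS, e.g. 3 CG sites in a
#' 397 bp neurotensin-receptor (Nts1) promoter window, 22 CG sites in a
#' 560 bp Pomc window, or 5 CG sites in a 342 bp Hsph1 window.
#'
#' @param length amplicon length in bp.
#' @param cgPositions integer vector of 0-based CG offsets, each in
#'   `[0, length - 2]`, non-overlapping (pairwise distance >= 2).
#' @param seed integer RNG seed.
#' @param name amplicon label.
#' @return An [AmpliconSpec-class] whose CG sites sit exactly at
#'   `cgPositions`.
#' @examples
#' nts1 <- makeAmplicon(397, cgPositions = c(60, 180, 300), seed = 7)
#' nrow(ampliconSites(nts1, "CG"))
#' @export
makeAmplicon <- function(length, cgPositions = integer(), seed = 1L,
                         name = "amplicon") {
  length <- as.integer(length)
  cgPositions <- sort(as.integer(cgPositions))
  if (length < 2L) stop("amplicon must be at least 2 bp")
  if (any(cgPositions < 0L | cgPositions > length - 2L)) {
    stop("cgPositions must lie in [0, length - 2]", call. = FALSE)
  }
  if (any(diff(cgPositions) < 2L)) {
    stop("cgPositions must not overlap (minimum spacing 2)", call. = FALSE)
  }
  chars <- with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    chars[cgPositions + 1L] <- "C"
    chars[cgPositions + 2L] <- "G"
    # Destroy accidental CG dinucleotides by mutating their G to A or T.
    # Planted positions hold C (never G at an accidental site's G slot), and
    # an A/T substitution can neither create a new CG nor touch a planted
    # one, so a single pass suffices.
    repeat {
      cg_at <- which(chars[-length] == "C" & chars[-1L] == "G")  # 1-based C pos
      cg_at <- setdiff(cg_at, cgPositions + 1L)
      if (!length(cg_at)) break
      chars[cg_at + 1L] <- sample(c("A", "T"), length(cg_at), replace = TRUE)
    }
    chars
  })
  AmpliconSpec(paste(chars, collapse = ""), name = name)
}

#' Convert an amplicon reference to bisulfite space
#'
#' Replaces every cytosine on the top strand by T (the fully converted,
#' fully unmethylated read sequence) and retains the mapping from the
#' converted coordinates back to the original cytosine offsets. Reads are
#' compared against this reference with C/T ambiguity at the recorded
#' positions.
#'
#' @param spec an [AmpliconSpec-class].
#' @return A list with `converted` (character string), and `cytosineOffsets`
#'   (0-based offsets that were C in the original reference; coordinates are
#'   unchanged by the in-place substitution).
#' @examples
#' convertReference(AmpliconSpec("ACGT"))
#' @export
convertReference <- function(spec) {
  stopifnot(is(spec, "AmpliconSpec"))
  ref <- as.character(spec@seq)
  list(converted = gsub("C", "T", ref, fixed = TRUE),
       cytosineOffsets = as.integer(spec@sites$offset))
}

#' Write / read an amplicon as FASTA plus a JSON site annotation sidecar
#'
#' @param spec an [AmpliconSpec-class].
#' @param fastaFile FASTA path; the sidecar is `<fastaFile>.sites.json`.
#' @return `writeAmplicon` invisibly returns the paths written;
#'   `readAmplicon` returns an [AmpliconSpec-class]. On read the sidecar is
#'   optional: absent, sites are re-annotated by a CG scan of the sequence,
#'   and present, it is checked against that scan.
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @export
writeAmplicon <- function(spec, fastaFile) {
  ss <- DNAStringSet(spec@seq)
  names(ss) <- spec@name
  writeXStringSet(ss, fastaFile)
  sidecar <- paste0(fastaFile, ".sites.json")
  jsonlite::write_json(
    list(name = spec@name,
         sites = as.data.frame(spec@sites),
         annotations = if (length(spec@annotations)) {
           data.frame(name = names(spec@annotations),
                      start = BiocGenerics::start(spec@annotations),
                      end = BiocGenerics::end(spec@annotations))
         } else NULL),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(fastaFile, sidecar))
}

#' @rdname writeAmplicon
#' @param fastaFile FASTA path to read.
#' @export
readAmplicon <- function(fastaFile) {
  ss <- readDNAStringSet(fastaFile)
  spec <- AmpliconSpec(as.character(ss[[1L]]), name = names(ss)[1L])
  sidecar <- paste0(fastaFile, ".sites.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    got <- as.data.frame(spec@sites)
    want <- as.data.frame(meta$sites)
    if (!identical(as.integer(want$offset), got$offset) ||
        !identical(as.character(want$context), got$context)) {
      stop("site sidecar disagrees with a CG scan of the FASTA sequence")
    }
    if (!is.null(meta$annotations) && NROW(meta$annotations)) {
      spec@annotations <- IRanges(start = meta$annotations$start,
                                  end = meta$annotations$end,
                                  names = meta$annotations$name)
    }
  }
  spec
}
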