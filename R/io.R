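## Plain-text readers/writers for the pipeline's standard formats: SIF
## networks with signed relations, GMT gene sets, expression/design tables,
## regulon and bioactivity tables, and ground-truth JSON.

#' Write a signed network as SIF
#'
#' Tab-separated \code{source  relation  target} with relation
#' \code{activates} or \code{inhibits}.
#'
#' @param network a [SignedNetwork-class].
#' @param file output path.
#' @export
writeSif <- function(network, file) {
    e <- edges(network)
    rel <- ifelse(e$sign == 1L, "activates", "inhibits")
    write.table(data.frame(e$from, rel, e$to), file, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read a signed network from SIF
#'
#' @param file path to a SIF file with relations \code{activates} /
#'   \code{inhibits}; other relations are an error.
#' @return A [SignedNetwork-class].
#' @export
readSif <- function(file) {
    d <- read.table(file, sep = "\t", header = FALSE,
                    col.names = c("from", "relation", "to"),
                    colClasses = "character")
    if (!all(d$relation %in% c("activates", "inhibits")))
        stop("unsigned or unknown relation in SIF: ",
             paste(setdiff(unique(d$relation),
                           c("activates", "inhibits")), collapse = ", "))
    SignedNetwork(data.frame(from = d$from, to = d$to,
                             sign = ifelse(d$relation == "activates",
                                           1L, -1L)))
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param file output path.
#' @param description per-set description column (recycled).
#' @export
writeGmt <- function(sets, file, description = "na") {
    lines <- vapply(names(sets), function(id)
        paste(c(id, description, sets[[id]]), collapse = "\t"),
        character(1))
    writeLines(lines, file)
    invisible(file)
}

#' Read a GMT gene-set collection
#'
#' @param file path to a GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-c(1L, 2L)])
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    sets
}

#' Write an expression matrix as TSV (gene rows, sample columns)
#'
#' @param mat genes x samples matrix.
#' @param file output path.
#' @export
writeExpressionTsv <- function(mat, file) {
    d <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read an expression TSV written by [writeExpressionTsv()]
#'
#' @param file input path.
#' @return genes x samples numeric matrix.
#' @export
readExpressionTsv <- function(file) {
    d <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d[[1L]]
    m
}

#' Write / read the factorial design table as CSV
#'
#' @param design design data.frame.
#' @param file path.
#' @export
writeDesignCsv <- function(design, file) {
    utils::write.csv(design, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' @rdname writeDesignCsv
#' @export
readDesignCsv <- function(file) {
    utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Write the planted ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param file path.
#' @export
writeGroundTruthJson <- function(truth, file) {
    jsonlite::write_json(
        list(regulators = plantedRegulators(truth),
             effectSize = truth@effectSize,
             perturbed = perturbedGenes(truth),
             enrichedSets = enrichedSets(truth),
             activeTargets = activeTargets(truth)),
        file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' Write a consensus subnetwork as SIF plus a node-attribute TSV
#'
#' @param subnetwork a [ConsensusSubnetwork-class].
#' @param sifFile path for the signed edge list.
#' @param nodeFile path for the node attribute table (node, role, state).
#' @export
writeSubnetwork <- function(subnetwork, sifFile, nodeFile) {
    e <- subnetwork@edges
    rel <- ifelse(e$sign == 1L, "activates", "inhibits")
    write.table(data.frame(e$from, rel, e$to), sifFile, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(subnetwork@nodes, nodeFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(sifFile)
}

#' Write / read a bioactivity corpus as CSV
#'
#' Columns: \code{compound_id}, \code{fingerprint_hex}, \code{target_id},
#' \code{activity_uM}.
#'
#' @param bio bioactivity data.frame as produced by
#'   [simulateAnnotations()] (columns compound, fingerprint, target,
#'   activity_uM).
#' @param file path.
#' @export
writeBioactivityCsv <- function(bio, file) {
    utils::write.csv(data.frame(compound_id = bio$compound,
                                fingerprint_hex = bio$fingerprint,
                                target_id = bio$target,
                                activity_uM = bio$activity_uM),
                     file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' @rdname writeBioactivityCsv
#' @export
readBioactivityCsv <- function(file) {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    data.frame(compound = d$compound_id, fingerprint = d$fingerprint_hex,
               target = d$target_id, activity_uM = d$activity_uM)
}
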