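#' Aggregate technical replicates into a per-animal abundance
#'
#' Each urine sample is injected three times; a protein's abundance for an
#' animal is the arithmetic mean of its spectral counts over the three
#' technical replicates, but only when the protein was observed (count > 0)
#' in all three. A protein absent from any replicate gets abundance 0 for
#' that animal — never a partial mean. Aggregates are kept at full
#' precision, not rounded.
#'
#' @param runs long-format `data.frame` for a single animal with columns
#'   `animal`, `replicate` (1..3), `accession`, `count`. A protein missing
#'   a row in some replicate is treated as count 0 there.
#' @return Named numeric vector, accession -> abundance, sorted by
#'   accession.
#' @examples
#' runs <- data.frame(animal = "sham_1", replicate = rep(1:3, 2),
#'                    accession = rep(c("A_RAT", "B_RAT"), each = 3),
#'                    count = c(10, 12, 14, 8, 9, 0))
#' aggregateTechnicalReplicates(runs)  # A_RAT 12, B_RAT 0
#' @export
aggregateTechnicalReplicates <- function(runs) {
    stopifnot(all(c("animal", "replicate", "accession", "count") %in%
                  colnames(runs)))
    animal <- unique(as.character(runs$animal))
    if (length(animal) != 1L)
        stop("expected runs for exactly one animal, got: ",
             paste(animal, collapse = ", "))
    reps <- sort(unique(runs$replicate))
    if (!identical(as.integer(reps), 1:3))
        stop(sprintf("animal '%s' must have exactly replicates 1, 2, 3",
                     animal))
    if (any(runs$count < 0) || anyNA(runs$count))
        stop(sprintf("negative or missing count for animal '%s'", animal))
    dup <- duplicated(runs[c("replicate", "accession")])
    if (any(dup))
        stop(sprintf("duplicate (replicate, accession) row for animal '%s'",
                     animal))

    acc <- sort(unique(as.character(runs$accession)))
    m <- matrix(0, nrow = length(acc), ncol = 3L,
                dimnames = list(acc, as.character(1:3)))
    m[cbind(match(as.character(runs$accession), acc),
            as.integer(runs$replicate))] <- runs$count
    present <- rowSums(m > 0) == 3L
    out <- ifelse(present, rowMeans(m), 0)
    names(out) <- acc
    out
}

#' Assemble the group-labelled count matrix
#'
#' Takes per-animal abundance vectors and the group design and builds a
#' [SpectralCountExperiment-class]: the union of accessions across animals
#' in lexicographic row order, missing entries filled with 0. No
#' between-sample normalisation is applied; the downstream 2-fold rule is
#' the analysis's guard against total-count differences between groups.
#'
#' @param perAnimal named list, animal id -> named abundance vector (as
#'   returned by [aggregateTechnicalReplicates()]).
#' @param design `data.frame` with columns `animal`, `group`; every design
#'   animal must appear in `perAnimal`, duplicates are an error.
#' @return A [SpectralCountExperiment-class] with columns in design order.
#' @export
buildCountMatrix <- function(perAnimal, design) {
    stopifnot(all(c("animal", "group") %in% colnames(design)))
    if (anyDuplicated(design$animal))
        stop("duplicate animal_id in design: ",
             design$animal[anyDuplicated(design$animal)])
    missing <- setdiff(design$animal, names(perAnimal))
    if (length(missing))
        stop("design animals without abundance data: ",
             paste(missing, collapse = ", "))
    perAnimal <- perAnimal[as.character(design$animal)]
    acc <- sort(unique(unlist(lapply(perAnimal, names), use.names = FALSE)))
    m <- matrix(0, nrow = length(acc), ncol = length(perAnimal),
                dimnames = list(acc, names(perAnimal)))
    for (a in names(perAnimal)) {
        v <- perAnimal[[a]]
        m[names(v), a] <- v
    }
    SpectralCountExperiment(m, group = design$group, animal = design$animal)
}

#' Count identified proteins in one run
#'
#' The per-run identification totals (how many accepted proteins have a
#' non-zero spectral count in an injection).
#'
#' @param counts named numeric vector, accession -> count, for one run.
#' @param accepted optional character vector of accepted accessions; when
#'   given only those are counted.
#' @return Integer count.
#' @export
countIdentifiedProteins <- function(counts, accepted = NULL) {
    nz <- names(counts)[counts > 0]
    if (!is.null(accepted)) nz <- intersect(nz, accepted)
    length(nz)
}
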