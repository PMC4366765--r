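# Run `code` under a local RNG seed, restoring the caller's RNG state.
# Seeds are explicit arguments throughout the package, never global state.
withSeed <- function(seed, code) {
    if (length(seed) != 1L || is.na(seed) || !is.numeric(seed))
        stop("'seed' must be a single non-NA integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Group a vector of per-animal values into a list of per-group vectors,
# ordered so that `control` comes first.
splitByGroup <- function(values, group, control = NULL) {
    g <- as.character(group)
    lv <- unique(g)
    if (!is.null(control)) {
        if (!control %in% lv) stop(sprintf("group '%s' not present", control))
        lv <- c(control, setdiff(lv, control))
    }
    lapply(lv, function(l) unname(values[g == l])) |> stats::setNames(lv)
}
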