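#' Import a per-sample clinical table
#'
#' Reads a comma-separated table whose header declares each column's type
#' with a prefix: \code{numeric:} (float fields, up to 40),
#' \code{cat:} (categorical fields, up to 20) and \code{series:}
#' (series-valued fields such as an audiogram, up to 9). A series cell
#' encodes ordered (x, y) pairs as \code{"x1=y1;x2=y2;..."} (e.g.
#' frequency in Hz = threshold in dB). Empty cells are explicit missing
#' values and are excluded from aggregation denominators.
#'
#' All series for a field share one x-grid within a cohort: the grid is
#' declared by the first sample carrying the field, and later samples on a
#' different grid are linearly interpolated onto it (flagged in the
#' stored rows).
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param path CSV file with a \code{sample_id} column and typed columns.
#' @return The updated warehouse.
#' @export
importClinical <- function(wh, path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!("sample_id" %in% names(df)))
        stop("clinical table requires a sample_id column")
    numCols <- grep("^numeric:", names(df), value = TRUE)
    catCols <- grep("^cat:", names(df), value = TRUE)
    serCols <- grep("^series:", names(df), value = TRUE)
    if (length(serCols) > 9)
        stop("clinical capacity exceeded: at most 9 series fields (got ",
             length(serCols), ")")
    if (length(numCols) > 40)
        stop("clinical capacity exceeded: at most 40 numeric fields (got ",
             length(numCols), ")")
    if (length(catCols) > 20)
        stop("clinical capacity exceeded: at most 20 categorical fields (got ",
             length(catCols), ")")
    unknown <- setdiff(names(df), c("sample_id", numCols, catCols, serCols))
    if (length(unknown))
        stop("clinical columns without a type prefix: ",
             paste(unknown, collapse = ", "))
    ids <- df$sample_id
    for (col in numCols) {
        field <- sub("^numeric:", "", col)
        v <- suppressWarnings(as.numeric(df[[col]]))
        keep <- !is.na(v)
        wh@clinicalNumeric <- rbind(wh@clinicalNumeric,
            data.frame(sample_id = ids[keep], field = field,
                       value = v[keep], stringsAsFactors = FALSE))
    }
    for (col in catCols) {
        field <- sub("^cat:", "", col)
        v <- trimws(df[[col]])
        keep <- !is.na(v) & nzchar(v)
        wh@clinicalCategorical <- rbind(wh@clinicalCategorical,
            data.frame(sample_id = ids[keep], field = field,
                       value = v[keep], stringsAsFactors = FALSE))
    }
    for (col in serCols) {
        field <- sub("^series:", "", col)
        for (i in seq_along(ids)) {
            cell <- df[[col]][i]
            if (is.na(cell) || !nzchar(trimws(cell))) next
            pairs <- strsplit(strsplit(cell, ";", fixed = TRUE)[[1]], "=",
                              fixed = TRUE)
            x <- as.numeric(vapply(pairs, `[`, "", 1L))
            y <- as.numeric(vapply(pairs, `[`, "", 2L))
            if (anyNA(x) || anyNA(y))
                stop("malformed series cell for sample ", ids[i],
                     " field ", field, ": ", cell)
            o <- order(x); x <- x[o]; y <- y[o]
            interpolated <- FALSE
            if (is.null(wh@seriesGrids[[field]])) {
                wh@seriesGrids[[field]] <- x
            } else if (!identical(wh@seriesGrids[[field]], x)) {
                grid <- wh@seriesGrids[[field]]
                y <- stats::approx(x, y, xout = grid, rule = 2)$y
                x <- grid
                interpolated <- TRUE
            }
            wh@clinicalSeries <- rbind(wh@clinicalSeries,
                data.frame(sample_id = ids[i], field = field, x = x, y = y,
                           interpolated = interpolated,
                           stringsAsFactors = FALSE))
        }
    }
    validObject(wh)
    wh
}

#' Carriers of a variant, variant set, or gene
#'
#' Case samples only by default, in deterministic (sample id) order. Gene
#' scope returns the union of carriers over all annotated variants of the
#' gene.
#'
#' @param wh an annotated \linkS4class{VariantWarehouse}.
#' @param variant variant key(s); a vector is treated as a variant set.
#' @param gene gene symbol (requires annotations).
#' @param includeControls also list control carriers.
#' @return data.frame (sample_id, zygosity), empty for unknown
#'   variants/genes.
#' @export
carriersOf <- function(wh, variant = NULL, gene = NULL,
                       includeControls = FALSE) {
    if (is.null(variant) == is.null(gene))
        stop("give exactly one of variant or gene")
    keys <- if (!is.null(variant)) variant
            else wh@annotations$key[wh@annotations$gene == gene]
    obs <- wh@observations[wh@observations$key %in% keys, , drop = FALSE]
    if (!includeControls) {
        caseIds <- wh@samples$sample_id[wh@samples$status == "case"]
        obs <- obs[obs$sample_id %in% caseIds, , drop = FALSE]
    }
    if (!nrow(obs))
        return(data.frame(sample_id = character(), zygosity = character(),
                          stringsAsFactors = FALSE))
    # one row per carrier; hom_alt dominates het across a variant set
    rank <- c(het = 1, hemizygous = 2, hom_alt = 3)
    best <- tapply(rank[obs$zygosity], obs$sample_id, max)
    out <- data.frame(sample_id = names(best),
                      zygosity = names(rank)[as.integer(best)],
                      stringsAsFactors = FALSE)
    out[order(out$sample_id), , drop = FALSE]
}

#' Averaged phenotype of a carrier set
#'
#' Aggregates the clinical profiles of the carriers of a variant, variant
#' set, or gene: numeric fields as mean and sample standard deviation
#' (n - 1 denominator; sd is missing when fewer than two carriers have a
#' value), categorical fields as frequency tables, series fields
#' pointwise on the cohort's shared x-grid. Missing values are excluded
#' from denominators.
#'
#' @param wh a \linkS4class{VariantWarehouse} with clinical data.
#' @param variant,gene carrier scope, as in [carriersOf()].
#' @param fields optional character vector restricting the aggregated
#'   fields.
#' @param survivorsOnly when aggregating at gene level, restrict to the
#'   supplied survivor keys (NULL = all annotated variants of the gene).
#' @return An \linkS4class{AggregatePhenotype}.
#' @export
aggregatePhenotype <- function(wh, variant = NULL, gene = NULL,
                               fields = NULL, survivorsOnly = NULL) {
    if (!is.null(gene) && !is.null(survivorsOnly)) {
        keys <- intersect(
            wh@annotations$key[wh@annotations$gene == gene], survivorsOnly)
        carriers <- carriersOf(wh, variant = keys)
        scope <- paste0("gene:", gene, " (survivors)")
    } else {
        carriers <- carriersOf(wh, variant = variant, gene = gene)
        scope <- if (!is.null(gene)) paste0("gene:", gene)
                 else paste(variant, collapse = "+")
    }
    ids <- carriers$sample_id
    if (!length(ids)) stop("no carriers for scope ", scope)
    pick <- function(df) {
        df <- df[df$sample_id %in% ids, , drop = FALSE]
        if (!is.null(fields)) df <- df[df$field %in% fields, , drop = FALSE]
        df
    }
    num <- pick(wh@clinicalNumeric)
    numAgg <- if (nrow(num)) {
        do.call(rbind, lapply(split(num$value, num$field), function(v)
            data.frame(mean = mean(v),
                       sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                       n = length(v))))
    } else data.frame(mean = numeric(), sd = numeric(), n = integer())
    numAgg <- cbind(data.frame(field = rownames(numAgg),
                               stringsAsFactors = FALSE), numAgg)
    rownames(numAgg) <- NULL
    cat_ <- pick(wh@clinicalCategorical)
    catAgg <- lapply(split(cat_$value, cat_$field), table)
    ser <- pick(wh@clinicalSeries)
    serAgg <- if (nrow(ser)) {
        parts <- lapply(split(ser, paste(ser$field, ser$x, sep = "\r")),
            function(g) data.frame(field = g$field[1], x = g$x[1],
                                   mean = mean(g$y),
                                   sd = if (nrow(g) >= 2) stats::sd(g$y)
                                        else NA_real_,
                                   n = nrow(g), stringsAsFactors = FALSE))
        out <- do.call(rbind, parts)
        out <- out[order(out$field, out$x), , drop = FALSE]
        rownames(out) <- NULL
        out
    } else data.frame(field = character(), x = numeric(), mean = numeric(),
                      sd = numeric(), n = integer(), stringsAsFactors = FALSE)
    new("AggregatePhenotype", scope = scope, numeric = numAgg,
        categorical = catAgg, series = serAgg,
        nCarriers = length(ids),
        interpolatedSamples = unique(ser$sample_id[ser$interpolated]))
}

#' Compare one case against an aggregated phenotype
#'
#' Per-field deviation report: the sample's value, the carrier-set mean
#' and standard deviation, and the z-score (value - mean) / sd where the
#' sd is defined. Fields with no value for the sample are omitted.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param sampleId the case to compare.
#' @param aggregate an \linkS4class{AggregatePhenotype}.
#' @return data.frame (field, value, mean, sd, z).
#' @export
compareCase <- function(wh, sampleId, aggregate) {
    if (!(sampleId %in% wh@samples$sample_id))
        stop("unknown sample: ", sampleId)
    num <- wh@clinicalNumeric
    num <- num[num$sample_id == sampleId, , drop = FALSE]
    agg <- aggregate@numeric
    m <- merge(num[c("field", "value")], agg, by = "field")
    if (!nrow(m))
        return(data.frame(field = character(), value = numeric(),
                          mean = numeric(), sd = numeric(), z = numeric(),
                          stringsAsFactors = FALSE))
    m$z <- ifelse(!is.na(m$sd) & m$sd > 0, (m$value - m$mean) / m$sd,
                  NA_real_)
    m[order(m$field), c("field", "value", "mean", "sd", "z"), drop = FALSE]
}

setMethod("show", "AggregatePhenotype", function(object) {
    cat(sprintf("AggregatePhenotype [%s], %d carrier(s)\n", object@scope,
                object@nCarriers))
    if (nrow(object@numeric)) {
        cat("  numeric fields:\n")
        for (i in seq_len(nrow(object@numeric)))
            cat(sprintf("    %-20s mean %.3f  sd %s  n %d\n",
                        object@numeric$field[i], object@numeric$mean[i],
                        ifelse(is.na(object@numeric$sd[i]), "NA",
                               sprintf("%.3f", object@numeric$sd[i])),
                        object@numeric$n[i]))
    }
    if (length(object@categorical))
        cat("  categorical fields:", paste(names(object@categorical),
                                           collapse = ", "), "\n")
    if (nrow(object@series))
        cat("  series fields:", paste(unique(object@series$field),
                                      collapse = ", "), "\n")
})
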