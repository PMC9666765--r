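# Post-SDM habitat computations: collinearity filtering of environmental
# variables, main-factor selection by cumulative contribution, suitability
# thresholding at 0.5, climate x soil x vegetation overlay (logical AND of
# limiting factors) and per-region area statistics.

#' Eliminate collinear environmental variables by Spearman correlation
#'
#' Pairwise Spearman rank correlations are computed among all candidate
#' variables; while any pair exceeds the threshold in absolute value, the
#' pair with the largest |rho| is processed (ties by column order) and its
#' lower-priority member dropped. Priority defaults to the table's column
#' order (earlier = more ecologically significant = kept); supply `priority`
#' to encode expert judgment. Constant columns have no defined rank
#' correlation; they are flagged and excluded from testing.
#'
#' @param table data.frame of observations x numeric environmental variables
#'   (>= 3 observations).
#' @param threshold |rho| above which a pair is considered collinear
#'   (default 0.8; strictly greater than).
#' @param priority character vector of variable names, most significant
#'   first; unlisted variables rank after listed ones in column order.
#' @return list with `retained` (character, in original column order),
#'   `dropped` (data.frame `dropped`, `kept`, `rho`), and `flagged`
#'   (constant columns).
#' @export
spearmanFilter <- function(table, threshold = 0.8, priority = NULL) {
  table <- as.data.frame(table)
  stopIf(nrow(table) < 3, "need at least 3 observations")
  stopIf(!all(vapply(table, is.numeric, TRUE)), "all columns must be numeric")
  vars <- colnames(table)
  stopIf(anyDuplicated(vars) > 0, "variable names must be unique")
  constant <- vars[vapply(table, function(v) stats::sd(v) == 0, TRUE)]
  if (length(constant))
    warning("constant column(s) excluded from correlation testing: ",
            paste(constant, collapse = ", "), call. = FALSE)
  active <- setdiff(vars, constant)
  prio <- match(vars, unique(c(priority, vars)))
  names(prio) <- vars
  rho <- if (length(active) >= 2)
    stats::cor(table[active], method = "spearman") else NULL
  dropped <- data.frame(dropped = character(), kept = character(),
                        rho = numeric())
  repeat {
    if (length(active) < 2) break
    r <- rho[active, active, drop = FALSE]
    diag(r) <- 0
    if (max(abs(r)) <= threshold) break
    hit <- which(abs(r) == max(abs(r)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- active[hit[1, 1]]; b <- active[hit[1, 2]]
    loser <- if (prio[a] <= prio[b]) b else a
    keeper <- if (loser == a) b else a
    dropped <- rbind(dropped, data.frame(dropped = loser, kept = keeper,
                                         rho = r[hit[1, 1], hit[1, 2]]))
    active <- setdiff(active, loser)
  }
  list(retained = vars[vars %in% c(active, constant)],
       dropped = dropped, flagged = constant)
}

#' Select main factors by cumulative contribution
#'
#' Variables are sorted by contribution (descending, ties keeping input
#' order) and the minimal prefix whose cumulative sum reaches the cutoff
#' share of the total is returned.
#'
#' @param contributions named non-negative numeric vector of percent
#'   contributions.
#' @param cutoff cumulative share required, in percent (default 85).
#' @return character vector of main-factor names, in descending
#'   contribution order.
#' @examples
#' selectMainFactors(c(a = 50, b = 30, c = 10, d = 10))  # a b c
#' @export
selectMainFactors <- function(contributions, cutoff = 85) {
  stopIf(length(contributions) == 0, "no contributions given")
  stopIf(any(contributions < 0), "contributions must be >= 0")
  stopIf(is.null(names(contributions)), "contributions must be named")
  ord <- order(-contributions)
  cum <- cumsum(contributions[ord])
  need <- cutoff / 100 * sum(contributions)
  k <- which(cum >= need)[1]
  names(contributions)[ord[seq_len(k)]]
}

#' Threshold a suitability raster into suitable / unsuitable
#'
#' A cell is suitable when its suitability index is greater than or equal
#' to the threshold (the 0.5 boundary itself is suitable); nodata cells are
#' preserved.
#'
#' @param raster a [SuitabilityRaster-class].
#' @param threshold suitability cut point (default 0.5, inclusive).
#' @return a [BinaryHabitatMap-class] with the same header.
#' @export
classifySuitability <- function(raster, threshold = 0.5) {
  g <- gridValues(raster)
  out <- ifelse(is.na(g), NA_real_, as.numeric(g >= threshold))
  BinaryHabitatMap(matrix(out, nrow(g), ncol(g)), gridHeaderOf(raster))
}

#' Overlay climate, soil and vegetation suitability
#'
#' A cell of the combined map is suitable if and only if it is suitable in
#' the climate layer AND in the soil layer AND its vegetation class is one
#' of the suitable types (limiting-factor semantics: each layer constrains
#' the habitat). A cell that is nodata in any layer is nodata in the result.
#'
#' @param climate,soil [BinaryHabitatMap-class] layers of matching shape.
#' @param vegetation integer class matrix of the same shape.
#' @param suitableClasses vegetation codes counted as suitable; the default
#'   `c(1, 2, 3)` encodes coniferous forest, mixed coniferous forest and
#'   broad-leaved forest under the fixture code list.
#' @return a [BinaryHabitatMap-class].
#' @export
overlayHabitat <- function(climate, soil, vegetation,
                           suitableClasses = c(1, 2, 3)) {
  cg <- gridValues(climate); sg <- gridValues(soil)
  stopIf(!all(dim(cg) == dim(sg)), "climate and soil shapes differ")
  stopIf(!all(dim(cg) == dim(vegetation)), "vegetation shape differs")
  vegOK <- matrix(vegetation %in% suitableClasses, nrow(cg), ncol(cg))
  out <- as.numeric(cg == 1 & sg == 1 & vegOK)
  out[is.na(cg) | is.na(sg) | is.na(vegetation)] <- NA_real_
  BinaryHabitatMap(matrix(out, nrow(cg), ncol(cg)), gridHeaderOf(climate))
}

#' Per-region suitable-habitat areas
#'
#' Counts suitable cells per region and converts to area. Suitable cells
#' whose region label is nodata are tallied under `"unassigned"` with a
#' warning. Areas are reported in 10^4 km^2, with a `"Total"` row equal to
#' the sum of all regions.
#'
#' @param map a [BinaryHabitatMap-class].
#' @param regions character matrix of region labels, same shape (`NA` =
#'   nodata).
#' @param cellAreaKm2 area of one cell in km^2 (> 0).
#' @return data.frame of class `"AreaTable"` with columns `region` and
#'   `area` (10^4 km^2), last row `"Total"`.
#' @export
areaStats <- function(map, regions, cellAreaKm2 = 1) {
  g <- gridValues(map)
  stopIf(!all(dim(g) == dim(regions)), "region grid shape differs")
  stopIf(cellAreaKm2 <= 0, "cellAreaKm2 must be > 0")
  suit <- !is.na(g) & g == 1
  lab <- regions[suit]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " suitable cell(s) lie outside any region; ",
            "tallied as 'unassigned'", call. = FALSE)
    lab[is.na(lab)] <- "unassigned"
  }
  counts <- table(lab)
  areas <- as.numeric(counts) * cellAreaKm2 / 1e4
  out <- data.frame(region = names(counts), area = areas,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(region = "Total", area = sum(areas)))
  structure(out, class = c("AreaTable", "data.frame"))
}

#' Build an AreaTable from known region areas
#'
#' Convenience constructor for area bookkeeping on published tables.
#'
#' @param areas named numeric vector of per-region areas in 10^4 km^2.
#' @param total optional printed total; defaults to `sum(areas)`.
#' @return an `"AreaTable"` data.frame.
#' @export
areaTable <- function(areas, total = sum(areas)) {
  stopIf(is.null(names(areas)), "areas must be named by region")
  structure(data.frame(region = c(names(areas), "Total"),
                       area = c(as.numeric(areas), total),
                       stringsAsFactors = FALSE),
            class = c("AreaTable", "data.frame"))
}

#' Share of a region group in a reference area
#'
#' 100 x sum(numerator areas) / denominator area. The raw percentage is
#' returned; for reporting, round half-up to integer percent with
#' [roundHalfUp()].
#'
#' @param table an `"AreaTable"`.
#' @param numerator region name(s) forming the numerator.
#' @param denominator a single region name or `"Total"` (default).
#' @return numeric percentage.
#' @export
shareOfTotal <- function(table, numerator, denominator = "Total") {
  miss <- setdiff(c(numerator, denominator), table$region)
  stopIf(length(miss) > 0, "region(s) not in table: ",
         paste(miss, collapse = ", "))
  num <- sum(table$area[table$region %in% numerator])
  den <- table$area[match(denominator, table$region)]
  stopIf(den == 0, "denominator area is zero")
  100 * num / den
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O
# ---------------------------------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `nodata_value`; case-insensitive) followed by the cell
#' matrix, row 1 = northernmost. Nodata cells become `NA`.
#'
#' @param path `.asc` file.
#' @param as `"grid"` (default) returns a [GridLayer-class];
#'   `"suitability"` validates values into a [SuitabilityRaster-class].
#' @return a [GridLayer-class] or [SuitabilityRaster-class].
#' @export
readAsciiGrid <- function(path, as = c("grid", "suitability")) {
  as <- match.arg(as)
  stopIf(!file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(header))
  stopIf(length(miss) > 0, "header misses: ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- header$nrows; nc <- header$ncols
  stopIf(length(vals) != nr * nc, "expected ", nr * nc, " cells, found ",
         length(vals))
  g <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == header$nodata_value] <- NA
  header <- gridHeader(nr, nc, header$xllcorner, header$yllcorner,
                       header$cellsize, header$nodata_value)
  if (as == "grid") GridLayer(g, header) else SuitabilityRaster(g, header)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [readAsciiGrid()]; header values round-trip exactly and `NA`
#' cells are written as the header's nodata value.
#'
#' @param x a [GridLayer-class] (or subclass).
#' @param path output `.asc` file.
#' @return invisibly, `path`.
#' @export
writeAsciiGrid <- function(x, path) {
  h <- gridHeaderOf(x)
  g <- gridValues(x)
  g[is.na(g)] <- h$nodata_value
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", fmt(h$ncols)),
               paste("nrows", fmt(h$nrows)),
               paste("xllcorner", fmt(h$xllcorner)),
               paste("yllcorner", fmt(h$yllcorner)),
               paste("cellsize", fmt(h$cellsize)),
               paste("NODATA_value", fmt(h$nodata_value))), con)
  writeLines(apply(g, 1, function(row) paste(fmt(row), collapse = " ")), con)
  invisible(path)
}
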