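# File formats: MetaImage grids, JSON plans, plain-text opening polygons,
# JSON physics-table containers, structured run reports.

#' Read and write MetaImage (.mhd/.raw) grids
#'
#' Minimal MetaImage support for 3D scalar volumes: a plain-text `.mhd`
#' header next to a raw little-endian data file. Values, origin, spacing and
#' dimensions round-trip losslessly (`MET_DOUBLE` storage by default;
#' `MET_FLOAT` is also read).
#'
#' @param grid A `vpmc_grid`.
#' @param path Path to the `.mhd` header; the `.raw` file is written next to
#'   it.
#' @param type `"MET_DOUBLE"` or `"MET_FLOAT"`.
#' @return `write_grid`: the path, invisibly. `read_grid`: a `vpmc_grid`.
#' @export
write_grid <- function(grid, path, type = c("MET_DOUBLE", "MET_FLOAT")) {
  type <- match.arg(type)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(grid$dims, collapse = " ")),
    paste("ElementSpacing =", paste(grid$spacing, collapse = " ")),
    paste("Offset =", paste(grid$origin, collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.double(grid$values), con,
           size = if (type == "MET_FLOAT") 4L else 8L, endian = "little")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("MetaImage header missing key: ", k)
    vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  type <- get("ElementType")
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported ElementType: ", type))
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  expected <- prod(dims) * size
  actual <- file.info(raw_path)$size
  if (is.na(actual) || actual != expected) {
    stop(sprintf("MetaImage size mismatch: header implies %d bytes, raw file has %s",
                 expected, ifelse(is.na(actual), "none", actual)))
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dims), size = size, endian = "little")
  vpmc_grid(array(v, dim = dims), origin, spacing)
}

#' Read and write plan files
#'
#' A plan is a JSON object with keys `machine` (`"AP"` or `"APRS"`),
#' `spots` (records with `energy`, `x`, `y`, `weight` and optional `sigma`)
#' and an optional `geometry` object (free-form keys such as
#' `opening_diameter` or a `polygon` path, passed through untouched).
#' Unknown top-level keys are rejected, energies must lie within the machine
#' span and weights must be nonnegative.
#'
#' @param path File path.
#' @param machine Machine name.
#' @param spots A [spot_list()].
#' @param geometry Optional geometry list stored verbatim.
#' @return `read_plan`: list with `machine`, `spots` and `geometry`
#'   (`NULL` if absent).
#' @export
write_plan <- function(path, machine, spots, geometry = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  body <- list(machine = machine, spots = as.data.frame(unclass(spots)))
  if (!is.null(geometry)) body$geometry <- geometry
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(p), c("machine", "spots", "geometry"))
  if (length(extra)) stop("unknown plan keys: ", paste(extra, collapse = ", "))
  if (!p$machine %in% c("AP", "APRS")) stop("machine must be AP or APRS")
  sp <- p$spots
  need <- c("energy", "x", "y", "weight")
  if (!all(need %in% names(sp))) {
    stop("plan spots need fields: ", paste(need, collapse = ", "))
  }
  if (is.null(sp$sigma)) sp$sigma <- in_air_sigma(sp$energy)
  list(machine = p$machine,
       spots = spot_list(sp$energy, sp$x, sp$y, sp$weight, sp$sigma),
       geometry = p$geometry)
}

#' Read dose-volume constraints from JSON
#'
#' The file holds an array of records mirroring the target-constraint table:
#' `kind` (V100/Dmin/CI/RHI), `soft`, `hard`, `direction`, optional
#' `weight`.
#'
#' @param path File path.
#' @return List of [dvc()] objects.
#' @export
read_dvcs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    dvc(r$kind, r$soft, r$hard %||% r$soft, r$direction,
        r$weight %||% 1)
  })
}

#' Read and write opening polygons
#'
#' Plain text, one "x y" vertex pair (mm) per line, implicitly closed; an
#' explicit closing vertex is dropped on read. Fewer than 3 distinct
#' vertices is a validation error.
#'
#' @param path File path.
#' @param polygon n x 2 vertex matrix (mm).
#' @return `read_polygon`: n x 2 matrix.
#' @export
write_polygon <- function(path, polygon) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(apply(as.matrix(polygon), 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_polygon
#' @export
read_polygon <- function(path) {
  m <- as.matrix(read.table(path, col.names = c("x", "y")))
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3) stop("polygon file must contain >= 3 distinct vertices")
  dimnames(m) <- NULL
  m
}

#' Persist physics tables
#'
#' All materials' tables live in one JSON container keyed by material name,
#' with per-material metadata (generation mode, seed, history count).
#'
#' @param tables Named list of `vpmc_tables`.
#' @param path File path.
#' @return `read_tables`: named list of `vpmc_tables`.
#' @export
write_tables <- function(tables, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(lapply(tables, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(t) {
    t$n_histories <- as.integer(t$n_histories)
    tab <- structure(t, class = "vpmc_tables")
    validate_tables(tab)
    tab
  })
  out
}

#' Write a structured run report
#'
#' Collects run provenance (engine, seed, particle counts, the statistical
#' uncertainty convention value) together with stage results (gamma settings
#' and pass rates, plan indices, timings) into one JSON report. Timings are
#' informational only.
#'
#' @param path Output path (directories are created).
#' @param ... Named report sections (lists or scalars).
#' @return The report list, invisibly.
#' @export
run_report <- function(path, ...) {
  rep <- list(...)
  rep$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(rep)
}
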