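#' Read spectra from the wide-CSV dialect
#'
#' One row per sample; reserved metadata columns (see [meta_columns()])
#' plus one numeric column per wavenumber, named by the wavenumber printed
#' with 6 significant digits. Ascending grids are reordered to descending.
#'
#' @param path file to read.
#' @param format only `"wide-csv"` is supported.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, format = "wide-csv") {
  format <- match.arg(format, "wide-csv")
  if (!file.exists(path)) stop("file not found: ", path)
  # fread warns about absent colClasses columns; missing metadata is
  # diagnosed explicitly below
  dt <- suppressWarnings(
    data.table::fread(path, sep = ",", header = TRUE,
                      colClasses = list(character = c(
                        "sample_id", "farm_id", "instrument_id",
                        "timestamp")),
                      data.table = FALSE, showProgress = FALSE))
  missing_cols <- setdiff(meta_columns(), names(dt))
  if (length(missing_cols)) {
    stop("format error: missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  spec_cols <- setdiff(names(dt), meta_columns())
  wn <- suppressWarnings(as.numeric(spec_cols))
  if (anyNA(wn)) {
    stop("format error: non-wavenumber spectral column name(s): ",
         paste(utils::head(spec_cols[is.na(wn)], 3L), collapse = ", "))
  }
  absorb <- dt[spec_cols]
  if (nrow(dt) > 0L) {
    for (j in seq_along(absorb)) {
      col <- absorb[[j]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
        stop("parse error: non-numeric absorbance at row ",
             if (length(bad)) bad[1L] else NA_integer_,
             ", column \"", spec_cols[j], "\"")
      }
    }
    absorb <- as.matrix(absorb)
  } else {
    absorb <- matrix(numeric(0), 0L, length(spec_cols))
  }
  spectrum_set(absorb, dt[meta_columns()], wn)
}

#' Write spectra in the wide-CSV dialect
#'
#' Numeric values are printed with `%.17g` so that a write/read/write
#' cycle is byte-identical (doubles round-trip exactly at 17 significant
#' digits).
#'
#' @param set a `spectrum_set`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  wn_names <- formatC(set$grid, digits = 6, format = "g", flag = "")
  meta <- set$meta
  out <- data.frame(
    sample_id = meta$sample_id,
    farm_id = meta$farm_id,
    instrument_id = meta$instrument_id,
    timestamp = format_timestamp(meta$timestamp),
    stringsAsFactors = FALSE
  )
  for (col in analyte_columns()) out[[col]] <- fmt_dbl(meta[[col]])
  if (n_samples(set) > 0L) {
    ab <- vapply(seq_len(n_points(set)),
                 function(j) fmt_dbl(set$absorbance[, j]),
                 character(n_samples(set)))
    if (n_samples(set) == 1L) ab <- matrix(ab, nrow = 1L)
    colnames(ab) <- wn_names
    out <- cbind(out, as.data.frame(ab, stringsAsFactors = FALSE))
  } else {
    for (nm in wn_names) out[[nm]] <- character(0)
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = ",", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

fmt_dbl <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load fitted models
#'
#' Models (screening, cluster, classifier) are stored as a single JSON
#' archive: a manifest (format version, stage, package version) plus all
#' numeric arrays at full precision. No executable serialisation format is
#' used, so archives are portable and safe to exchange.
#'
#' @param model a fitted `screening_model`, `cluster_model` or
#'   `classifier_model`.
#' @param path archive path (conventionally `.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model with its class restored.
#' @export
save_model <- function(model, path) {
  stage <- class(model)[1L]
  if (!stage %in% c("screening_model", "cluster_model", "classifier_model")) {
    stop("not a saveable model: ", stage)
  }
  archive <- list(
    manifest = list(
      format_version = MODEL_FORMAT_VERSION,
      stage = stage,
      package = "milkscreen",
      package_version = as.character(utils::packageVersion("milkscreen"))
    ),
    payload = ms_encode(model)
  )
  json <- jsonlite::toJSON(archive, digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  archive <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                       simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop("integrity error: model archive unreadable (",
                             conditionMessage(e), ")")
  )
  if (is.null(archive$manifest) || is.null(archive$payload)) {
    stop("integrity error: archive lacks manifest/payload")
  }
  ver <- archive$manifest$format_version
  if (!identical(as.integer(ver), MODEL_FORMAT_VERSION)) {
    stop("version mismatch: archive format ", ver,
         ", this package reads format ", MODEL_FORMAT_VERSION)
  }
  ms_decode(archive$payload)
}

# -- typed JSON encoding ------------------------------------------------
# Every R object is wrapped as {"t": <type>, ...} so matrices, arrays,
# classes and POSIXct survive the round trip at full double precision.

ms_encode <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.function(x)) stop("refusing to serialise a function")
  if (inherits(x, "POSIXct")) {
    return(list(t = "time", v = format_timestamp(x)))
  }
  if (is.data.frame(x)) {
    return(list(t = "df", cols = lapply(as.list(x), ms_encode)))
  }
  if (is.list(x)) {
    return(list(t = "list", cls = class_or_null(x),
                names = names2(x), items = lapply(x, ms_encode)))
  }
  if (is.array(x) || is.matrix(x)) {
    return(list(t = "array", mode = storage.mode(x), dim = dim(x),
                dimnames = encode_dimnames(dimnames(x)),
                v = encode_atomic(as.vector(x))))
  }
  if (is.atomic(x)) {
    return(list(t = "vec", mode = storage.mode(x), names = names2(x),
                v = encode_atomic(unname(x))))
  }
  stop("unsupported type in model archive: ", class(x)[1L])
}

ms_decode <- function(x) {
  switch(x$t,
    "null" = NULL,
    "time" = parse_timestamp(unlist(x$v)),
    "df" = {
      cols <- lapply(x$cols, ms_decode)
      as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
    },
    "list" = {
      out <- lapply(x$items, ms_decode)
      if (!is.null(x$names)) names(out) <- unlist(x$names)
      if (!is.null(x$cls)) class(out) <- unlist(x$cls)
      out
    },
    "array" = {
      v <- decode_atomic(x$v, x$mode)
      dim(v) <- unlist(x$dim)
      dimnames(v) <- decode_dimnames(x$dimnames)
      v
    },
    "vec" = {
      v <- decode_atomic(x$v, x$mode)
      if (!is.null(x$names)) names(v) <- unlist(x$names)
      v
    },
    stop("integrity error: unknown node type '", x$t, "'")
  )
}

# doubles are printed as %.17g strings so archives round-trip bit-exactly
# (plain JSON numbers lose the last couple of significant digits)
encode_atomic <- function(v) {
  if (is.double(v)) fmt_dbl(v) else v
}

decode_atomic <- function(v, mode) {
  if (!length(v)) return(vector(mode, 0L))
  v <- unlist(lapply(v, function(x) if (is.null(x)) NA else x))
  if (mode == "double") {
    out <- suppressWarnings(as.numeric(v))
    out[v == "NA"] <- NA_real_
    return(out)
  }
  storage.mode(v) <- mode
  v
}

class_or_null <- function(x) {
  cls <- class(x)
  if (identical(cls, "list")) NULL else cls
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) NULL else as.list(nm)
}

encode_dimnames <- function(dn) {
  if (is.null(dn)) return(NULL)
  lapply(dn, function(d) if (is.null(d)) list() else as.list(d))
}

decode_dimnames <- function(dn) {
  if (is.null(dn)) return(NULL)
  out <- lapply(dn, function(d) if (length(d)) unlist(d) else NULL)
  if (all(vapply(out, is.null, logical(1L)))) NULL else out
}
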