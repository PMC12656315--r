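#' Default indicator polarity map
#'
#' Polarity states whether larger values of an indicator are better
#' (`"more_is_better"`) or worse (`"less_is_better"`) for soil quality.
#' Exchangeable acidity and its components, bulk density and the fractal
#' dimension are adverse; everything else is beneficial by default.
#'
#' @param overrides named character vector of polarity overrides.
#' @return named character vector mapping indicator name to polarity.
#' @export
default_polarity <- function(overrides = NULL) {
  less <- c("EA", "ExH", "ExAl", "BD", "D")
  pol <- setNames(rep("more_is_better", length(soil_indicators())),
                  soil_indicators())
  pol[names(pol) %in% less] <- "less_is_better"
  if (!is.null(overrides)) {
    bad <- setdiff(overrides, c("more_is_better", "less_is_better"))
    if (length(bad) > 0) {
      stop("unknown polarity value(s): ", paste(bad, collapse = ", "))
    }
    pol[names(overrides)] <- overrides
  }
  pol
}

#' Canonical soil indicator names
#' @return character vector of the indicator columns the pipeline knows.
#' @export
soil_indicators <- function() {
  c("pH", "EA", "ExH", "ExAl", "CEC", "ExK", "ExNa", "ExCa", "ExMg",
    "TEB", "SOM", "TN", "TP", "TK", "AN", "AP", "AK", "CAT", "UE",
    "BD", "R0.25", "MWD", "GMD", "D")
}

design_columns <- function() c("plot_id", "treatment", "crop_season", "replicate")

treatment_levels <- function() c("CK", "PTs-1", "PTs-2", "PTs-3")
season_levels <- function() c("LAP", "ESP", "SM")

#' Validate a soil sample table
#'
#' Checks design columns, factor levels, numeric indicator values with no
#' missing entries, uniqueness of plot ids within season, and (when
#' present) that TEB equals the exchangeable base-cation sum
#' ExK + ExNa + ExCa + ExMg to within 1e-9.
#'
#' @param x data.frame with design columns and indicator columns.
#' @return `x` invisibly, with class `soil_table` prepended.
#' @export
validate_soil_table <- function(x) {
  miss <- setdiff(design_columns(), names(x))
  if (length(miss) > 0) {
    stop("missing design column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) stop("soil table has no rows")
  bad_t <- setdiff(unique(x$treatment), treatment_levels())
  if (length(bad_t) > 0) {
    stop("unknown treatment label(s): ", paste(bad_t, collapse = ", "))
  }
  bad_s <- setdiff(unique(x$crop_season), season_levels())
  if (length(bad_s) > 0) {
    stop("unknown crop_season label(s): ", paste(bad_s, collapse = ", "))
  }
  key <- paste(x$plot_id, x$crop_season)
  if (anyDuplicated(key)) stop("duplicate plot_id within a crop_season")
  ind <- setdiff(names(x), design_columns())
  for (col in ind) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      stop("non-numeric value in indicator column '", col, "'")
    }
    if (anyNA(v)) {
      stop("missing value in indicator column '", col, "' (row ",
           which(is.na(v))[1], ")")
    }
  }
  cats <- c("ExK", "ExNa", "ExCa", "ExMg")
  if ("TEB" %in% names(x) && all(cats %in% names(x))) {
    s <- x$ExK + x$ExNa + x$ExCa + x$ExMg
    if (any(abs(x$TEB - s) > 1e-9)) {
      stop("TEB does not equal ExK + ExNa + ExCa + ExMg (row ",
           which(abs(x$TEB - s) > 1e-9)[1], ")")
    }
  }
  if (!inherits(x, "soil_table")) class(x) <- c("soil_table", class(x))
  invisible(x)
}

#' Check that a design is balanced
#'
#' @param x soil table.
#' @return TRUE if every treatment x season cell holds the same number of
#'   replicates.
#' @export
is_balanced_design <- function(x) {
  tab <- table(x$treatment, x$crop_season)
  length(unique(as.vector(tab))) == 1
}

#' Read a soil property table from TSV
#'
#' One header row; design columns `plot_id`, `treatment`, `crop_season`,
#' `replicate` plus numeric indicator columns. Unknown indicators are
#' kept with polarity `more_is_better` and a warning.
#'
#' @param path TSV file path.
#' @param polarity named polarity vector; defaults to [default_polarity()].
#' @return validated `soil_table` data.frame with a `polarity` attribute.
#' @export
read_soil_table <- function(path, polarity = default_polarity()) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.delim(path, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("empty soil table: ", path)
  ind <- setdiff(names(x), design_columns())
  for (col in ind) {
    v <- x[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !anyNA(v)) {
        stop("non-numeric cell in column '", col, "', row ",
             which(is.na(conv))[1])
      }
      x[[col]] <- conv
    }
  }
  unknown <- setdiff(ind, names(polarity))
  if (length(unknown) > 0) {
    warning("unknown indicator(s) kept with polarity more_is_better: ",
            paste(unknown, collapse = ", "))
    polarity[unknown] <- "more_is_better"
  }
  x <- validate_soil_table(x)
  attr(x, "polarity") <- polarity[ind]
  x
}

#' Write a soil table to TSV
#' @param x soil table.
#' @param path output path.
#' @export
write_soil_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sieve fraction set
#'
#' Masses retained on an ordered (descending) sieve stack plus the pan.
#'
#' @param apertures sieve openings in mm, strictly decreasing.
#' @param masses grams retained per fraction; `length(apertures) + 1`
#'   values, the last being the pan (< smallest aperture).
#' @param assumed_max_diameter upper bound of the coarsest fraction (mm).
#'   Defaults to 5 mm: material above 5 mm is removed by dry pre-sieving.
#' @param sample_id optional sample label.
#' @return object of class `sieve_fractions`.
#' @export
sieve_fractions <- function(apertures, masses, assumed_max_diameter = 5,
                            sample_id = NA_character_) {
  if (length(apertures) < 1) stop("need at least one aperture")
  if (any(diff(apertures) >= 0)) stop("apertures must be strictly decreasing")
  if (length(masses) != length(apertures) + 1) {
    stop("need length(apertures) + 1 masses (pan included)")
  }
  if (any(masses < 0)) stop("masses must be non-negative")
  if (sum(masses) <= 0) stop("total mass must be positive")
  if (assumed_max_diameter < apertures[1]) {
    stop("assumed_max_diameter below the coarsest aperture")
  }
  structure(list(apertures = as.numeric(apertures),
                 masses = as.numeric(masses),
                 assumed_max_diameter = assumed_max_diameter,
                 sample_id = sample_id),
            class = "sieve_fractions")
}

#' Read sieve fraction data from CSV
#'
#' Long format: columns `sample_id`, `aperture_mm` (a number or the word
#' `pan`), `mass_g`. Returns one `sieve_fractions` object per sample.
#'
#' @param path CSV file.
#' @param assumed_max_diameter coarsest-fraction upper bound in mm.
#' @return named list of `sieve_fractions`.
#' @export
read_sieve_csv <- function(path, assumed_max_diameter = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "aperture_mm", "mass_g")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(x, x$sample_id), function(d) {
    is_pan <- tolower(d$aperture_mm) == "pan"
    if (sum(is_pan) != 1) stop("sample ", d$sample_id[1], ": need exactly one pan row")
    ap <- as.numeric(d$aperture_mm[!is_pan])
    o <- order(ap, decreasing = TRUE)
    sieve_fractions(ap[o], c(d$mass_g[!is_pan][o], d$mass_g[is_pan]),
                    assumed_max_diameter, d$sample_id[1])
  })
  out[unique(x$sample_id)]
}

#' Write sieve fraction sets to CSV
#' @param sets named list of `sieve_fractions`.
#' @param path output CSV path.
#' @export
write_sieve_csv <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(sample_id = s$sample_id,
               aperture_mm = c(as.character(s$apertures), "pan"),
               mass_g = s$masses, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an amplicon feature table from TSV
#'
#' Rows are taxa (first column taxon ids), columns are samples, values
#' non-negative integer counts.
#'
#' @param path TSV file.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return integer matrix of class `feature_table` with a `kingdom`
#'   attribute and per-taxon kingdom vector.
#' @export
read_feature_table <- function(path, kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.delim(path, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("feature table needs a taxon column and >= 2 samples")
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) stop("duplicate taxon id: ", ids[duplicated(ids)][1])
  if (anyDuplicated(names(x)[-1])) stop("duplicate sample id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric count in feature table")
  if (any(m < 0)) stop("negative count in feature table")
  if (any(m != floor(m))) stop("non-integer count in feature table")
  rownames(m) <- ids
  feature_table(m, kingdom = rep(kingdom, nrow(m)))
}

#' Construct a feature table
#' @param counts numeric matrix, taxa x samples, non-negative integers.
#' @param kingdom per-taxon kingdom labels (recycled if length 1).
#' @return `feature_table` matrix.
#' @export
feature_table <- function(counts, kingdom = "bacteria") {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon rownames and sample colnames")
  }
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != floor(counts))) stop("counts must be integers")
  kingdom <- rep(kingdom, length.out = nrow(counts))
  structure(counts, kingdom = kingdom, class = c("feature_table", "matrix"))
}

#' Write a feature table to TSV
#' @param ft feature table.
#' @param path output path.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(taxon_id = rownames(ft), as.data.frame(unclass(ft)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-occurrence network to GraphML
#'
#' Node attributes: kingdom, module, Zi, Pi, role, degree. Edge
#' attributes: correlation and sign. Re-reading with
#' [read_network_graphml()] reproduces the topology exactly.
#'
#' @param net `cooccurrence_network` (see [build_network()]).
#' @param path output file.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nodes <- net$nodes
  fill <- function(col, proto) {
    if (is.null(nodes[[col]])) rep(proto, nrow(nodes)) else nodes[[col]]
  }
  nodes$module <- fill("module", NA_integer_)
  nodes$zi <- fill("zi", NA_real_)
  nodes$pi <- fill("pi", NA_real_)
  nodes$role <- fill("role", NA_character_)
  net$nodes <- nodes
  g <- network_as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by [write_network_graphml()]
#' @param path GraphML file.
#' @return `cooccurrence_network`.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    return(structure(list(
      nodes = data.frame(id = character(), kingdom = character(),
                         degree = integer(), module = integer(),
                         zi = numeric(), pi = numeric(),
                         role = character(), stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         r = numeric(), p = numeric(), sign = character(),
                         stringsAsFactors = FALSE),
      modularity = NA_real_), class = "cooccurrence_network"))
  }
  nodes <- data.frame(id = igraph::V(g)$name,
                      kingdom = igraph::V(g)$kingdom,
                      degree = igraph::degree(g),
                      module = igraph::V(g)$module,
                      zi = igraph::V(g)$zi,
                      pi = igraph::V(g)$pi,
                      role = igraph::V(g)$role,
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        r = igraph::E(g)$r, p = igraph::E(g)$p,
                        sign = igraph::E(g)$sign, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        r = numeric(), p = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 modularity = NA_real_), class = "cooccurrence_network")
}

network_as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}
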