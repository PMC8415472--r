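# Embedded physico-chemical constants for the 20 standard amino acids.
# Column order: molecular mass (Da), solvent-accessible surface (A^2),
# volume (A^3), hydropathy index, normalized hydrophobicity, solubility
# (g/kg H2O), octanol-interface / octanol / interface transfer free energies
# (kcal/mol), isoelectric point at 25 C, pKa of the alpha-amino and
# alpha-carboxyl groups. Values are stored exactly as measured/published;
# glutamate (E) and glutamine (Q) rows are keyed by one-letter code.
.aa_property_matrix <- local({
  m <- matrix(c(
    #  mass,  surf,  vol,  hyd,  hyph,  sol,  oct-if,  oct,  ifc,   pI, pKaN, pKaC
    89.094, 115,  88.6,  1.8, 0.616, 166.9,  0.33,  0.50,  0.17,  6.11,  9.87, 2.35,  # A
    174.203, 225, 173.4, -4.5, 0.000, 182.6,  1.00,  1.81,  0.81, 10.76,  9.09, 2.18,  # R
    132.119, 150, 111.1, -3.5, 0.236,  25.1,  0.43,  0.85,  0.42, 10.76,  8.80, 2.02,  # N
    133.104, 160, 114.1, -3.5, 0.028,  5.04,  2.41,  3.64,  1.23,  2.98,  9.60, 1.88,  # D
    121.154, 135, 108.5,  2.5, 0.680, 277.0,  0.22, -0.02, -0.24,  5.02, 10.78, 1.71,  # C
    147.131, 190, 138.4, -3.5, 0.043,   8.6,  0.19,  0.77,  0.58,  3.08,  9.67, 2.19,  # E
    146.146, 180, 143.8, -3.5, 0.251,  42.0,  1.61,  3.63,  2.02,  5.65,  9.13, 2.17,  # Q
    75.067,  75,  60.1, -0.4, 0.501, 239.0,  1.14,  1.15,  0.01,  6.06,  9.60, 2.34,  # G
    155.156, 195, 153.2, -3.2, 0.165,  43.5,  1.37,  2.33,  0.96,  7.64,  8.97, 1.78,  # H
    131.175, 175, 166.7,  4.5, 0.943,  34.2, -0.81, -1.12, -0.31,  6.04,  9.76, 2.32,  # I
    131.175, 170, 166.7,  3.8, 0.943,  23.8, -0.69, -1.25, -0.56,  6.04,  9.60, 2.36,  # L
    146.189, 200, 168.6, -3.9, 0.283,   5.8,  1.81,  2.80,  0.99,  9.47, 10.28, 2.18,  # K
    149.208, 185, 162.9,  1.9, 0.738,  56.0, -0.44, -0.67, -0.23,  5.74,  9.21, 2.28,  # M
    165.192, 210, 189.9,  2.8, 1.000,  27.9, -0.58, -1.71, -1.13,  5.91,  9.24, 2.58,  # F
    115.132, 145, 112.7, -1.6, 0.711,  50.0, -0.31,  0.14,  0.45,  6.30, 10.60, 1.99,  # P
    105.093, 115,  89.0, -0.8, 0.359, 250.0,  0.33,  0.46,  0.13,  5.68,  9.15, 2.21,  # S
    119.119, 140, 116.1, -0.7, 0.450,  90.6,  0.11,  0.25,  0.14,  5.60,  9.12, 2.15,  # T
    204.228, 225, 227.8, -0.9, 0.878,  13.2, -0.24, -2.09, -1.85,  5.88,  9.39, 2.38,  # W
    181.191, 230, 193.6, -1.3, 0.880,  0.51,  0.23, -0.71, -0.94,  5.63,  9.11, 2.20,  # Y
    117.148, 155, 140.0,  4.2, 0.825,  88.0, -0.53, -0.46,  0.07,  6.02,  9.72, 2.29   # V
  ), nrow = 20, byrow = TRUE)
  rownames(m) <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  colnames(m) <- c("molecular_mass", "surface", "volume", "hydropathy_index",
                   "hydrophobicity", "solubility", "octanol_interface",
                   "octanol", "interface", "pI_25C", "pKa_NH2", "pKa_COOH")
  m
})

.aa_property_units <- c(
  molecular_mass = "Da", surface = "Å²", volume = "Å³",
  hydropathy_index = "dimensionless", hydrophobicity = "dimensionless",
  solubility = "g/kg H2O", octanol_interface = "kcal/mol",
  octanol = "kcal/mol", interface = "kcal/mol", pI_25C = "pH units",
  pKa_NH2 = "pH units", pKa_COOH = "pH units")

#' Names of the supported amino-acid properties
#'
#' @return Character vector of the property identifiers embedded in the
#'   package, in table column order.
#' @export
property_names <- function() colnames(.aa_property_matrix)

#' Default property set for relatedness and tree analyses
#'
#' The five properties used throughout the default analyses: volume,
#' hydropathy index, solubility, octanol-interface transfer free energy, and
#' isoelectric point at 25 C.
#'
#' @return Character vector of five property names.
#' @export
default_properties <- function() {
  c("volume", "hydropathy_index", "solubility", "octanol_interface", "pI_25C")
}

#' Load one embedded amino-acid property table
#'
#' Returns the residue-to-value map for one measured physico-chemical
#' property of the 20 standard amino acids. Values are embedded constants;
#' no file access is involved.
#'
#' @param property_name One of [property_names()].
#' @return An object of class `aa_property_table`: a list with elements
#'   `property`, `units`, and `values` (named numeric vector of length 20,
#'   keyed by one-letter residue code). Subsetting with `[` looks residues
#'   up and fails on any non-standard letter.
#' @examples
#' vol <- load_property_table("volume")
#' vol["G"]   # 60.1
#' @export
load_property_table <- function(property_name) {
  if (!is.character(property_name) || length(property_name) != 1L ||
      !(property_name %in% colnames(.aa_property_matrix))) {
    stop("unknown property '", paste(property_name, collapse = ","),
         "'; valid options: ",
         paste(colnames(.aa_property_matrix), collapse = ", "))
  }
  structure(
    list(property = property_name,
         units = unname(.aa_property_units[[property_name]]),
         values = .aa_property_matrix[, property_name]),
    class = "aa_property_table")
}

#' @export
`[.aa_property_table` <- function(x, i) {
  v <- x$values[i]
  if (anyNA(v) || is.null(names(v)) || any(names(v) == "") || anyNA(names(v))) {
    bad <- if (is.character(i)) i[!(i %in% names(x$values))] else i
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         " for property '", x$property, "'")
  }
  v
}

#' @export
print.aa_property_table <- function(x, ...) {
  cat("Amino-acid property table: ", x$property, " [", x$units, "]\n", sep = "")
  print(x$values)
  invisible(x)
}

#' Load a user property table from TSV
#'
#' Reads a table in the same schema that [write_property_tsv()] emits
#' (a `residue` column plus one numeric column per property) and returns
#' one column as an `aa_property_table`. All 20 standard residues must be
#' present.
#'
#' @param path Path to the TSV file.
#' @param property_name Column to extract.
#' @param units Units string recorded on the returned table.
#' @return An `aa_property_table`.
#' @export
read_property_table_tsv <- function(path, property_name, units = "user-defined") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!("residue" %in% names(df))) stop("property TSV must have a 'residue' column")
  if (!(property_name %in% names(df))) {
    stop("column '", property_name, "' not found in ", path)
  }
  std <- rownames(.aa_property_matrix)
  if (!setequal(df$residue, std)) {
    stop("property TSV must key exactly the 20 standard residues")
  }
  vals <- stats::setNames(as.numeric(df[[property_name]]), df$residue)[std]
  structure(list(property = property_name, units = units, values = vals),
            class = "aa_property_table")
}

#' Export the embedded property constants as TSV
#'
#' Writes the full 20-residue x 12-property table, one row per residue,
#' reproducing the embedded constants exactly.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_property_tsv <- function(path) {
  df <- data.frame(residue = rownames(.aa_property_matrix),
                   .aa_property_matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gapped protein sequence record
#'
#' @param taxon Taxon label.
#' @param letters Character scalar over the 20 one-letter residue codes plus
#'   the gap symbols `-` and `.`; lowercase accepted and normalized.
#' @return Object of class `gapped_seq` with elements `taxon` and `letters`
#'   (normalized: uppercase, gaps as `-`).
#' @export
gapped_sequence <- function(taxon, letters) {
  letters <- normalize_letters(letters)
  structure(list(taxon = as.character(taxon), letters = letters,
                 length = nchar(letters)),
            class = "gapped_seq")
}

# Uppercase and map the '.' gap dialect to '-'; validation happens at encode
# time so the offending position can be reported.
normalize_letters <- function(letters) {
  stopifnot(is.character(letters), length(letters) == 1L)
  gsub(".", "-", toupper(letters), fixed = TRUE)
}

.residue_codes <- function() rownames(.aa_property_matrix)

#' Encode a gapped sequence as a number string
#'
#' Replaces each residue letter by the measured value of one physico-chemical
#' property and each alignment gap by 0, producing the numeric profile
#' ("number string") on which all downstream analyses operate.
#'
#' @param seq A `gapped_seq`, or a plain character scalar of letters.
#' @param table An `aa_property_table` (see [load_property_table()]), or a
#'   property name.
#' @return Numeric vector of class `encoded_seq`, one value per alignment
#'   position (1-based), with attributes `taxon` and `property`.
#' @examples
#' encode_sequence("GA-", "volume")   # 60.1 88.6 0.0
#' @export
encode_sequence <- function(seq, table) {
  if (is.character(table)) table <- load_property_table(table)
  stopifnot(inherits(table, "aa_property_table"))
  taxon <- NA_character_
  if (inherits(seq, "gapped_seq")) {
    taxon <- seq$taxon
    letters <- seq$letters
  } else {
    letters <- normalize_letters(seq)
  }
  chars <- strsplit(letters, "", fixed = TRUE)[[1]]
  ok <- chars %in% c(.residue_codes(), "-")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop("unknown symbol '", chars[i], "' at position ", i,
         " (allowed: 20 standard residues, '-', '.')")
  }
  vals <- numeric(length(chars))
  res <- chars != "-"
  vals[res] <- unname(table$values[chars[res]])
  structure(vals, taxon = taxon, property = table$property,
            class = "encoded_seq")
}

#' Decode a number string back to letters
#'
#' Inverts [encode_sequence()] where the property admits it: zeros map to
#' gaps and every non-zero value must equal one of the 20 table constants.
#' Only properties whose 20 values are all distinct are invertible;
#' solubility is the only embedded column with that guarantee (isoleucine
#' and leucine share identical volume and molecular mass, and arginine's
#' hydrophobicity of 0 collides with the gap code).
#'
#' @param values Numeric vector as produced by [encode_sequence()].
#' @param table The `aa_property_table` used for encoding (or its name).
#' @return Character scalar of letters with gaps as `-`.
#' @export
decode_sequence <- function(values, table) {
  if (is.character(table)) table <- load_property_table(table)
  out <- rep("-", length(values))
  nz <- which(values != 0)
  if (length(nz)) {
    idx <- match(values[nz], table$values)
    if (anyNA(idx)) {
      stop("value ", values[nz][which(is.na(idx))[1]],
           " is not a table constant for property '", table$property, "'")
    }
    out[nz] <- names(table$values)[idx]
  }
  paste(out, collapse = "")
}

#' Encode every sequence of an alignment under several properties
#'
#' @param seqs An `alignment_set` (see [read_alignment()]), a list of
#'   `gapped_seq` objects, or a named character vector of aligned letters.
#' @param properties Character vector of property names; defaults to the
#'   five-property set of [default_properties()].
#' @return A nested list `enc[[taxon]][[property]]` of `encoded_seq`
#'   vectors, classed `encoded_set`, with attributes `taxa`, `properties`
#'   and `width`.
#' @export
encode_alignment <- function(seqs, properties = default_properties()) {
  seqs <- as_alignment_set(seqs)
  widths <- nchar(seqs$seqs)
  if (length(unique(widths)) > 1L) {
    stop("sequences are not aligned; lengths differ: ",
         paste(sprintf("%s=%d", seqs$taxa, widths), collapse = ", "))
  }
  tables <- lapply(properties, load_property_table)
  enc <- lapply(seq_along(seqs$taxa), function(i) {
    g <- gapped_sequence(seqs$taxa[i], seqs$seqs[i])
    stats::setNames(lapply(tables, function(tb) encode_sequence(g, tb)),
                    properties)
  })
  names(enc) <- seqs$taxa
  structure(enc, taxa = seqs$taxa, properties = properties,
            width = seqs$width, class = "encoded_set")
}

#' @export
print.encoded_set <- function(x, ...) {
  cat("Encoded alignment: ", length(attr(x, "taxa")), " taxa x ",
      length(attr(x, "properties")), " properties, width ",
      attr(x, "width"), "\n", sep = "")
  cat("taxa: ", paste(attr(x, "taxa"), collapse = ", "), "\n", sep = "")
  cat("properties: ", paste(attr(x, "properties"), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
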