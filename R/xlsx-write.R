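# Minimal OOXML (.xlsx) writer.
#
# No spreadsheet-writing package and no external `zip` binary are available in
# the deployment image, so the workbook container is assembled directly: a ZIP
# archive with stored (uncompressed) entries, one worksheet, inline-string
# header cells and numeric data cells. readxl reads it back; the test suite
# uses that round trip as the correctness check.

crc32_int <- function(data) {
  hx <- digest::digest(data, algo = "crc32", serialize = FALSE)
  # via double arithmetic: CRCs >= 2^31 overflow strtoi's integer range
  sum(strtoi(strsplit(hx, "")[[1]], 16L) *
        16^(rev(seq_len(nchar(hx))) - 1))
}

# little-endian byte encodings; u32 goes through doubles so values >= 2^31 work
zip_u16 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

zip_u32 <- function(x) {
  x <- as.numeric(x)
  b <- raw(4)
  for (i in 1:4) {
    b[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  b
}

# entries: named list of character scalars (name -> file content)
zip_write_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  central <- list()
  pos <- 0
  for (nm in names(entries)) {
    data <- charToRaw(entries[[nm]])
    name <- charToRaw(nm)
    crc <- crc32_int(data)
    n <- length(data)
    local_header <- c(
      zip_u32(0x04034b50), zip_u16(20), zip_u16(0), zip_u16(0),
      zip_u16(0), zip_u16(0), zip_u32(crc), zip_u32(n), zip_u32(n),
      zip_u16(length(name)), zip_u16(0)
    )
    writeBin(c(local_header, name, data), con)
    central[[nm]] <- c(
      zip_u32(0x02014b50), zip_u16(20), zip_u16(20), zip_u16(0), zip_u16(0),
      zip_u16(0), zip_u16(0), zip_u32(crc), zip_u32(n), zip_u32(n),
      zip_u16(length(name)), zip_u16(0), zip_u16(0), zip_u16(0), zip_u16(0),
      zip_u32(0), zip_u32(pos), name
    )
    pos <- pos + length(local_header) + length(name) + n
  }
  cd <- do.call(c, unname(central))
  writeBin(cd, con)
  end_record <- c(
    zip_u32(0x06054b50), zip_u16(0), zip_u16(0),
    zip_u16(length(entries)), zip_u16(length(entries)),
    zip_u32(length(cd)), zip_u32(pos), zip_u16(0)
  )
  writeBin(end_record, con)
  invisible(path)
}

xlsx_sheet_xml <- function(df) {
  cols <- names(df)
  col_letters <- LETTERS[seq_along(cols)]
  header <- paste0(
    '<row r="1">',
    paste0('<c r="', col_letters, '1" t="inlineStr"><is><t>', cols,
           "</t></is></c>", collapse = ""),
    "</row>"
  )
  rows <- character(0)
  if (nrow(df) > 0) {
    r <- seq_len(nrow(df)) + 1L
    cells <- vapply(seq_along(cols), function(j) {
      paste0('<c r="', col_letters[j], r, '"><v>',
             sprintf("%.10g", df[[j]]), "</v></c>")
    }, character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df))
    rows <- paste0('<row r="', r, '">',
                   apply(cells, 1, paste0, collapse = ""), "</row>")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", header, paste(rows, collapse = ""), "</sheetData></worksheet>"
  )
}

# df: data.frame of numeric columns; written as the single sheet "points"
write_minimal_xlsx <- function(df, path) {
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"
  )
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  )
  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="points" sheetId="1" r:id="rId1"/></sheets></workbook>'
  )
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"
  )
  entries <- list(
    "[Content_Types].xml" = ct,
    "_rels/.rels" = rels,
    "xl/workbook.xml" = wb,
    "xl/_rels/workbook.xml.rels" = wb_rels,
    "xl/worksheets/sheet1.xml" = xlsx_sheet_xml(df)
  )
  zip_write_stored(entries, path)
}
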