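minimal_bioc <- function() {
  '<?xml version="1.0" encoding="UTF-8"?>
<collection><source>plantchem</source>
 <document><id>15493960</id>
  <passage>
   <offset>0</offset>
   <text>Pomegranate contains anthocyanins.</text>
   <annotation id="T1"><infon key="type">plant</infon>
     <infon key="identifier">NA</infon>
     <location offset="0" length="11"/><text>Pomegranate</text></annotation>
   <annotation id="T2"><infon key="type">chemical</infon>
     <infon key="identifier">MeSH:D000872</infon>
     <location offset="21" length="12"/><text>anthocyanins</text></annotation>
   <relation id="R1"><infon key="type">POS</infon>
     <infon key="weak_trigger">contains</infon>
     <infon key="strong_trigger">contains</infon>
     <node refid="T1" role="plant"/><node refid="T2" role="chemical"/></relation>
  </passage>
 </document>
</collection>'
}

test_that("a minimal BioC file yields one document with one POS unit", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_bioc(), path)
  corpus <- read_bioc(path)
  expect_length(corpus, 1L)
  expect_equal(corpus[[1L]]$doc$pmid, "15493960")
  expect_length(corpus[[1L]]$units, 1L)
  u <- corpus[[1L]]$units[[1L]]
  expect_equal(u$label, "POS")
  expect_equal(u$plant$text, "Pomegranate")
  expect_equal(u$chemical$ids, "MeSH:D000872")
  expect_equal(u$weak_trigger, "contains")
  expect_equal(u$strong_trigger, "contains")
})

test_that("BioC reader enforces relation/annotation referential integrity", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(gsub('refid="T2"', 'refid="T9"', minimal_bioc()), path)
  expect_error(read_bioc(path), "missing chemical annotation")
  writeLines(sub("</collection>", "", minimal_bioc()), path)
  expect_error(read_bioc(path))  # malformed XML surfaces the parser error
})

test_that("triggers are carried only on POS relations", {
  fx <- table1_fixtures()
  docs <- fixtures_to_docs(fx)
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioc(docs, path)
  back <- read_bioc(path)
  units <- unlist(lapply(back, `[[`, "units"), recursive = FALSE)
  for (u in units) {
    if (u$label == "POS") {
      expect_false(is.null(u$weak_trigger))
      expect_false(is.null(u$strong_trigger))
    } else {
      expect_null(u$weak_trigger)
      expect_null(u$strong_trigger)
    }
  }
})

test_that("writing an empty corpus gives a valid zero-document file", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioc(list(), path)
  expect_length(read_bioc(path), 0L)
})

test_that("BioC round-trip is lossless and canonical on generated corpora", {
  fx <- generate_units(50, 0.5, 0.1, seed = 11)
  docs <- fixtures_to_docs(fx)
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioc(docs, path)
  back <- read_bioc(path)
  expect_equal(plantchem:::canon_docs(back), plantchem:::canon_docs(docs))
  # writer output is a fixed point: re-writing the re-read corpus is
  # byte-identical
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_bioc(back, path2)
  expect_identical(readLines(path2, warn = FALSE), readLines(path, warn = FALSE))
})

test_that("writer refuses a POS unit stripped of its triggers", {
  fx <- table1_fixtures()[[1L]]
  u <- fx$unit
  u$weak_trigger <- NULL       # violate the invariant behind the API's back
  docs <- list(list(doc = abstract_doc(u$pmid, u$sentence$text,
                                       list(u$sentence)),
                    units = list(u)))
  expect_error(write_bioc(docs, withr::local_tempfile()), "missing a trigger")
})

test_that("one sentence with two plants exports as two rows sharing the Sentence cell", {
  text <- "Effects of nitrogen on masson pine (Pinus massoniana) seedlings."
  plex <- load_name_lexicon(plantchem_extdata("plants_fixture.tsv"), "PLANT")
  clex <- load_name_lexicon(plantchem_extdata("chemicals_fixture.tsv"), "CHEMICAL")
  doc <- annotate_abstract(abstract_doc("24283344", text, split_sentences(text)),
                           plex, clex)
  units <- expand_units(doc$sentences[[1L]], pmid = "24283344")
  expect_length(units, 2L)
  lines <- export_sheet(units)
  expect_equal(lines[[1L]], paste(sheet_columns(), collapse = "\t"))
  cells <- lapply(strsplit(lines[-1L], "\t"), function(x) { length(x) <- 15L; x })
  expect_equal(cells[[1L]][[11L]], text)
  expect_equal(cells[[2L]][[11L]], text)
  expect_setequal(vapply(cells, `[[`, character(1), 1L),
                  c("masson pine", "Pinus massoniana"))
  expect_equal(vapply(cells, `[[`, character(1), 6L), rep("nitrogen", 2L))
})

test_that("zero units export as a header-only sheet", {
  expect_equal(export_sheet(list()), paste(sheet_columns(), collapse = "\t"))
})

test_that("sheet round-trip is lossless on generated units", {
  fx <- generate_units(100, 0.4, 0.1, seed = 23)
  units <- lapply(fx, `[[`, "unit")
  back <- import_sheet(export_sheet(units))
  expect_equal(plantchem:::canon_units(back), plantchem:::canon_units(units))
})

test_that("NEG rows import with absent triggers and checks are preserved", {
  fx <- generate_units(10, 0, 0, seed = 5)
  u <- fx[[1L]]$unit
  u$provenance$p_check <- "O"; u$provenance$c_check <- "X"
  u$provenance$c_note <- "span corrected"
  back <- import_sheet(export_sheet(list(u)))[[1L]]
  expect_equal(back$label, "NEG")
  expect_null(back$weak_trigger)
  expect_null(back$strong_trigger)
  expect_equal(back$provenance$p_check, "O")
  expect_equal(back$provenance$c_check, "X")
  expect_equal(back$provenance$c_note, "span corrected")
})

test_that("sheet import validates offsets, labels and POS triggers row by row", {
  fx <- table1_fixtures()
  lines <- export_sheet(list(fx[[1L]]$unit))
  bad <- sub("^Pomegranate", "Pineapple+++", lines[[2L]])  # same length, wrong text
  expect_error(import_sheet(c(lines[[1L]], bad)), "row 2")
  cells <- strsplit(lines[[2L]], "\t")[[1L]]; length(cells) <- 15L
  cells[is.na(cells)] <- ""
  cells[[14L]] <- ""                                       # POS without weak trigger
  expect_error(import_sheet(c(lines[[1L]], paste(cells, collapse = "\t"))),
               "POS unit with missing trigger")
  expect_error(import_sheet(c("Wrong\theader", lines[[2L]])), "canonical column")
})
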