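Package: regindex
Title: Regulation Index Analysis of Closed-Chamber Respirometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify hypoxia tolerance of aquatic ectotherms from
    closed-chamber respirometry. Raw oxygen-decline traces are trimmed,
    blank-corrected and converted to mass-specific rate-vs-oxygen profiles;
    each profile is summarised by the Regulation Index (RI), the spline
    area-under-curve of the response located between perfect oxyconformity
    (RI = 0) and perfect oxyregulation (RI = 1), extended to negative values
    for metabolic suppression. Group-level medians and quartiles are
    classified into respiration strategies, and groups are compared with the
    tie-corrected Kruskal-Wallis test plus a rank-based multiple-comparison
    post hoc with compact letter display. A synthetic-trace simulator with
    analytically known RI provides ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
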