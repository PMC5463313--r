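Package: shamtdm
Title: Sham Therapeutic Drug Monitoring Results for Blinded Dose
    Individualisation in Randomised Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for maintaining double-blinding in placebo-controlled
    trials of drugs that require therapeutic drug monitoring (TDM). Sham
    plasma concentrations for placebo participants are simulated in real
    time by rejection sampling from a Gaussian fitted sequentially to the
    accruing treatment-arm concentrations, truncated to the therapeutic
    window, with a protocol-sanctioned adjustable lower threshold.
    Includes rule-based dose individualisation under linear
    pharmacokinetics (initiation by body weight, scaling toward a target
    concentration, adverse-event hold, usual-dose ceiling with
    adherence-note fallback), a re-blinding workflow that merges true and
    sham values into a single arm-free report with full audit logging,
    blinding diagnostics, and a synthetic two-arm trial generator so the
    entire workflow is testable without trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
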