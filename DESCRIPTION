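Package: capgap
Title: Capability-Gap Analysis for Virtual Orthopedic Surgery Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalizes muscle-tendon parameters and motor control of a
    polyline musculoskeletal model from gait, EMG and clinical range-of-motion
    data, applies parametric virtual orthopedic surgeries (osteotomies, muscle
    transfers, patella advancement, force scaling), and quantifies pre- and
    post-operative gait performance as the capability gap: the reserve joint
    moments needed to achieve a typically-developing gait pattern under
    synergy-constrained static optimization with rigid-tendon Hill muscles.
    Includes seeded synthetic gait fixtures with known ground truth, muscle
    synergy extraction by non-negative matrix factorization with bootstrap
    model-order selection, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    nloptr,
    quadprog,
    stats,
    tools,
    utils,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
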