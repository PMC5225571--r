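# Default diagnosis category map.
#
# physical: the 13 broad ICD-9-CM chapters used for physical comorbidity,
#   each a list of inclusive 3-digit-root ranges.
# psychiatric: named categories defined by code prefixes.  A prefix with a
#   decimal part ("296.2") matches that code and any further subdivision
#   ("296.21"); a bare 3-digit root ("311") matches the root and all its
#   decimals.  These groupings are conventional, not normative: substitute
#   your own file to change them.
# unions: derived categories defined as the union of other psychiatric
#   categories (a code in any member also carries the union label).
index:
  code: "301.83"
  label: "BPD"
physical:
  - name: "Infectious and parasitic"
    ranges: [[1, 139]]
  - name: "Neoplasm"
    ranges: [[140, 239]]
  - name: "Endocrine, metabolic and immunity"
    ranges: [[240, 279]]
  - name: "Blood and blood-forming organs"
    ranges: [[280, 289]]
  - name: "Nervous system and sense organs"
    ranges: [[320, 389]]
  - name: "Circulatory system"
    ranges: [[390, 459]]
  - name: "Respiratory system"
    ranges: [[460, 519]]
  - name: "Digestive system"
    ranges: [[520, 579]]
  - name: "Genitourinary system"
    ranges: [[580, 629]]
  - name: "Skin and subcutaneous tissue"
    ranges: [[680, 709]]
  - name: "Musculoskeletal system"
    ranges: [[710, 739]]
  - name: "Congenital anomalies"
    ranges: [[740, 759]]
  - name: "Injury and poisoning"
    ranges: [[800, 999]]
psychiatric:
  "Depressive disorder": ["296.2", "296.3", "300.4", "311"]
  "Bipolar disorder": ["296.0", "296.1", "296.4", "296.5", "296.6", "296.7", "296.8"]
  "Anxiety disorder": ["300.0", "300.2", "300.3", "308.3", "309.81"]
  "Sleep disorder": ["307.4", "327", "780.5"]
  "Alcohol use disorder": ["303", "305.0"]
  "Opioid use disorder": ["304.0", "305.5"]
  "Amphetamine use disorder": ["304.4", "305.7"]
  "ADHD": ["314"]
  "Mental retardation": ["317", "318", "319"]
  "Autistic spectrum disorder": ["299"]
  "Eating disorder": ["307.1", "307.5"]
unions:
  "Substance use disorder":
    ["Alcohol use disorder", "Opioid use disorder", "Amphetamine use disorder"]
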