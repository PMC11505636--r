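items:
  diet_content:
    item_id: diet_content
    level_labels:
    - low consumption of sugars
    - moderate consumption of sugars
    - high consumption of sugars
    - severe consumption of sugars
    level_points:
    - 0
    - 1
    - 2
    - 3
  diet_frequency:
    item_id: diet_frequency
    level_labels:
    - 0-3 meals
    - 4-5 meals
    - 6-7 meals
    - more than 7 meals
    level_points:
    - 0
    - 1
    - 2
    - 3
  hygiene_habits:
    item_id: hygiene_habits
    level_labels:
    - brushing 3 times a day performed by a parent
    - brushing 2 times a day performed by a parent
    - brushing 2 times a day with supervision
    - brushing 1-2 times a day without supervision/no brushing
    level_points:
    - 0
    - 1
    - 2
    - 3
  fluoride_program:
    item_id: fluoride_program
    level_labels:
    - fluoride toothpaste + fluoride mouthwash + fluoride os (in the past)
    - fluoride toothpaste + fluoride os (in the past)
    - fluoride toothpaste
    - absence of fluoride program
    level_points:
    - 0
    - 1
    - 2
    - 3
  family_susceptibility:
    item_id: family_susceptibility
    level_labels:
    - mother - father -
    - mother + father -
    - mother ++ father +/-
    - mother ++ father ++
    level_points:
    - 0
    - 1
    - 2
    - 3
  caries_experience:
    item_id: caries_experience
    level_labels:
    - absence of caries + no old restorations + absence of teeth missing due to caries
    - 1 or 2 caries (or restorations or teeth missing due to caries)
    - 2 to 4 caries (or restorations or teeth missing due to caries)
    - 4 or more caries (or restorations or teeth missing due to caries)
    level_points:
    - 0
    - 1
    - 2
    - 3
  oral_hygiene_status:
    item_id: oral_hygiene_status
    level_labels:
    - no plaque
    - plaque without bleeding
    - plaque with bleeding, calculus, marginal gingivitis
    - plaque with bleeding, calculus, gingivitis in multiple sites
    level_points:
    - 0
    - 1
    - 2
    - 3
  ph_test:
    item_id: ph_test
    level_labels:
    - alkaline pH (>7)
    - neutral pH (7)
    - acidic pH (6.5-5.5)
    - critical pH (<5.5)
    level_points:
    - 0
    - 1
    - 2
    - 3
thresholds:
  label:
  - Low
  - Moderate
  - High
  - Very High
  min:
  - 0
  - 6
  - 11
  - 16
  max:
  - 5
  - 10
  - 15
  - 24
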