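# SYNTHETIC normative reference table. The original age- and gender-specific
# norms come from an unpublished reference survey and are not available;
# this stand-in was generated from plausible gamma-distributed weekly-drinks
# samples and RSOD band shares (see read_norms() for the schema).
strata:
  male:
    15-16:
      weekly_drinks:
      - 0
      - 1
      - 1
      - 7
      - 2
      - 7
      - 0
      - 8
      - 0
      - 6
      - 1
      - 5
      - 4
      - 0
      - 1
      - 0
      - 2
      - 6
      - 5
      - 16
      - 24
      - 5
      - 6
      - 2
      - 17
      - 6
      - 7
      - 5
      - 1
      - 7
      - 10
      - 2
      - 7
      - 1
      - 5
      - 3
      - 25
      - 1
      - 7
      - 4
      rsod_band_counts:
        NONE: 12
        ONE_TO_TWO: 12
        MORE_THAN_TWO: 16
    17-18:
      weekly_drinks:
      - 50
      - 11
      - 16
      - 9
      - 1
      - 6
      - 40
      - 5
      - 14
      - 4
      - 5
      - 12
      - 3
      - 25
      - 13
      - 8
      - 1
      - 14
      - 1
      - 1
      - 26
      - 0
      - 2
      - 0
      - 1
      - 0
      - 1
      - 2
      - 8
      - 18
      - 4
      - 15
      - 27
      - 21
      - 1
      - 11
      - 21
      - 36
      - 20
      - 1
      rsod_band_counts:
        NONE: 12
        ONE_TO_TWO: 12
        MORE_THAN_TWO: 16
    19-20:
      weekly_drinks:
      - 5
      - 16
      - 54
      - 6
      - 7
      - 15
      - 23
      - 10
      - 36
      - 50
      - 6
      - 4
      - 22
      - 9
      - 15
      - 79
      - 24
      - 8
      - 20
      - 4
      - 5
      - 8
      - 6
      - 1
      - 45
      - 19
      - 4
      - 13
      - 27
      - 2
      - 17
      - 5
      - 3
      - 5
      - 16
      - 9
      - 53
      - 43
      - 3
      - 8
      rsod_band_counts:
        NONE: 12
        ONE_TO_TWO: 12
        MORE_THAN_TWO: 16
    21+:
      weekly_drinks:
      - 1
      - 25
      - 8
      - 7
      - 35
      - 12
      - 0
      - 15
      - 4
      - 0
      - 18
      - 6
      - 8
      - 15
      - 6
      - 0
      - 28
      - 11
      - 3
      - 0
      - 11
      - 0
      - 15
      - 1
      - 2
      - 2
      - 1
      - 29
      - 0
      - 1
      - 5
      - 6
      - 10
      - 10
      - 5
      - 1
      - 4
      - 6
      - 9
      - 7
      rsod_band_counts:
        NONE: 12
        ONE_TO_TWO: 12
        MORE_THAN_TWO: 16
  female:
    15-16:
      weekly_drinks:
      - 8
      - 4
      - 1
      - 0
      - 1
      - 2
      - 0
      - 4
      - 14
      - 5
      - 3
      - 5
      - 8
      - 0
      - 4
      - 2
      - 1
      - 0
      - 5
      - 18
      - 1
      - 0
      - 0
      - 0
      - 0
      - 0
      - 11
      - 0
      - 0
      - 0
      - 1
      - 0
      - 0
      - 7
      - 7
      - 4
      - 5
      - 16
      - 5
      - 4
      rsod_band_counts:
        NONE: 18
        ONE_TO_TWO: 13
        MORE_THAN_TWO: 9
    17-18:
      weekly_drinks:
      - 0
      - 3
      - 1
      - 3
      - 2
      - 1
      - 4
      - 18
      - 6
      - 0
      - 1
      - 1
      - 7
      - 2
      - 2
      - 14
      - 12
      - 7
      - 4
      - 5
      - 0
      - 16
      - 4
      - 1
      - 12
      - 4
      - 4
      - 1
      - 5
      - 2
      - 10
      - 2
      - 7
      - 23
      - 11
      - 5
      - 12
      - 2
      - 3
      - 0
      rsod_band_counts:
        NONE: 18
        ONE_TO_TWO: 13
        MORE_THAN_TWO: 9
    19-20:
      weekly_drinks:
      - 0
      - 11
      - 1
      - 16
      - 0
      - 1
      - 13
      - 10
      - 5
      - 5
      - 9
      - 1
      - 12
      - 3
      - 0
      - 3
      - 1
      - 1
      - 1
      - 2
      - 0
      - 10
      - 12
      - 1
      - 4
      - 5
      - 0
      - 3
      - 1
      - 5
      - 1
      - 0
      - 18
      - 0
      - 6
      - 1
      - 8
      - 9
      - 7
      - 9
      rsod_band_counts:
        NONE: 18
        ONE_TO_TWO: 13
        MORE_THAN_TWO: 9
    21+:
      weekly_drinks:
      - 11
      - 2
      - 22
      - 22
      - 9
      - 9
      - 9
      - 2
      - 9
      - 1
      - 5
      - 14
      - 8
      - 15
      - 5
      - 13
      - 5
      - 4
      - 5
      - 11
      - 7
      - 2
      - 11
      - 2
      - 1
      - 24
      - 2
      - 0
      - 0
      - 3
      - 6
      - 0
      - 0
      - 5
      - 6
      - 19
      - 2
      - 2
      - 13
      - 17
      rsod_band_counts:
        NONE: 18
        ONE_TO_TWO: 13
        MORE_THAN_TWO: 9
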