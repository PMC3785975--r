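# Built-in English SMS template bank. One weekly template per content
# category (ids 1-10) plus drinking-day strategy templates. Placeholders in
# {braces} are filled from tailoring_vars().
templates:
  - id: w01
    slot: weekly
    category_id: 1
    risk_groups: [NON_RISK, LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. Alcohol is packed with calories and slows the burning of
      fat, so regular drinking adds up on the scale. Cutting back keeps you
      fitter.
  - id: w02
    slot: weekly
    category_id: 2
    risk_groups: [NON_RISK, LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. You decide what you drink, not your friends. Saying no to a
      round shows character and often earns respect. Only do what feels
      right to you.
  - id: w03
    slot: weekly
    category_id: 3
    risk_groups: [NON_RISK, LOW_RISK, HIGH_RISK]
    text: >-
      Hey {name}. Even small amounts of alcohol raise your risk of accidents
      on the road. Without alcohol in your blood you are always safer, on
      foot, by bike or behind the wheel.
  - id: w04
    slot: weekly
    category_id: 4
    risk_groups: [NON_RISK]
    text: >-
      Hi {name}. Great that you keep your drinking sensible. More energy,
      better sleep and a clear head the next morning are yours to keep.
  - id: w05
    slot: weekly
    category_id: 5
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. Drinking less pays off fast: you feel fitter the next day
      and keep a clear head. Give it a try this week.
  - id: w06
    slot: weekly
    category_id: 6
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hello {name}. Trouble with parents, friends or school after drinking
      is avoidable. Keep in mind that you can dodge these problems by
      drinking less or not at all.
  - id: w07
    slot: weekly
    category_id: 7
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hey {name}. You recently had {max_drinks} drinks on one occasion. Your
      blood alcohol was around {bac_permille} per mille that time. At that
      level you risk blackouts, shallow breathing and loss of reflexes.
      Watch out!
  - id: w08
    slot: weekly
    category_id: 8
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. Downing many drinks in one evening hits your body hardest:
      accidents, memory gaps and alcohol poisoning all become much more
      likely. Pace yourself.
  - id: w09
    slot: weekly
    category_id: 9
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. Reducing your drinking is a smart decision for you. Less
      alcohol means more energy, more money and better days after.
  - id: w10
    slot: weekly
    category_id: 10
    risk_groups: [HIGH_RISK]
    text: >-
      Hi {name}. Concerned about your own drinking or a friend's? Talking
      helps. A local outpatient alcohol counseling service can support you,
      confidentially and free of charge.
  - id: d01
    slot: drinking_day
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hey {name}. Soft drinks now and then are good for your body: they
      quench thirst, deliver minerals and keep you from getting drunk too
      quickly tonight.
  - id: d02
    slot: drinking_day
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. Decide before you go out how many drinks you will have
      tonight, and stick to it. Alternating with water makes it easy.
  - id: d03
    slot: drinking_day
    risk_groups: [LOW_RISK, HIGH_RISK]
    text: >-
      Hi {name}. Eat well before you head out tonight: a full stomach slows
      the alcohol down, and you stay in control of your evening.
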