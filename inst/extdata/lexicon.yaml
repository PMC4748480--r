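# Bundled lexicon: 13 dictionaries used by the Step-1 rules.
# Keys are matched case-insensitively; multi-word keys are matched
# longest-first by the d() rule constituent.  Payload conventions:
#   doseUnit        -> canonical singular unit token
#   latinFrequency  -> administrations per day (number)
#   timeUnit/timeUnitLy/perTimeUnit -> canonical time unit (hour/day/week/month)
#   period          -> interval in days (number)
#   number          -> numeric value
#   mealExpression  -> administrations per day implied (3 general, 1 individual)
#   asRequired/asDirected/timeOfDay/verb/rangeOperator -> marker (value unused)
verb:
  take: verb
  taken: verb
  taking: verb
  apply: verb
  applied: verb
  use: verb
  used: verb
  inhale: verb
  insert: verb
  instil: verb
  instill: verb
  swallow: verb
  chew: verb
  give: verb
doseUnit:
  tablet: tablet
  tablets: tablet
  tab: tablet
  tabs: tablet
  capsule: capsule
  capsules: capsule
  cap: capsule
  caps: capsule
  ml: ml
  mls: ml
  millilitre: ml
  millilitres: ml
  milliliter: ml
  milliliters: ml
  spoonful: spoonful
  spoonfuls: spoonful
  spoonsful: spoonful
  spoonsfuls: spoonful
  drop: drop
  drops: drop
  puff: puff
  puffs: puff
  mg: mg
  milligram: mg
  milligrams: mg
  g: g
  gram: g
  grams: g
  mcg: mcg
  microgram: mcg
  micrograms: mcg
  pill: pill
  pills: pill
  sachet: sachet
  sachets: sachet
  patch: patch
  patches: patch
  suppository: suppository
  suppositories: suppository
  pessary: pessary
  pessaries: pessary
  inhalation: inhalation
  inhalations: inhalation
  application: application
  applications: application
latinFrequency:
  od: 1
  bd: 2
  bid: 2
  tds: 3
  tid: 3
  qds: 4
  qid: 4
  once: 1
  twice: 2
  thrice: 3
timeUnit:
  hour: hour
  hours: hour
  hr: hour
  hrs: hour
  h: hour
  day: day
  days: day
  week: week
  weeks: week
  wk: week
  wks: week
  month: month
  months: month
timeUnitLy:
  hourly: hour
  hrly: hour
  daily: day
  nightly: day
  weekly: week
  monthly: month
perTimeUnit:
  a day: day
  per day: day
  each day: day
  every day: day
  a week: week
  per week: week
  each week: week
  every week: week
  a month: month
  per month: month
  every month: month
  a night: day
  per night: day
  an hour: hour
  per hour: hour
period:
  alternate days: 2
  alternate nights: 2
  alternate mornings: 2
  every other day: 2
  every other night: 2
number:
  one: 1
  two: 2
  three: 3
  four: 4
  five: 5
  six: 6
  seven: 7
  eight: 8
  nine: 9
  ten: 10
  eleven: 11
  twelve: 12
  fifteen: 15
  twenty: 20
  half: 0.5
  quarter: 0.25
rangeOperator:
  to: range
  or: range
  "-": range
  up to: open
  upto: open
  between: between
  and: between_and
asRequired:
  prn: as_required
  sos: as_required
  when required: as_required
  if required: as_required
  as required: as_required
  when needed: as_required
  if needed: as_required
  as needed: as_required
  as necessary: as_required
  if necessary: as_required
  when necessary: as_required
asDirected:
  as directed: as_directed
  as advised: as_directed
  as instructed: as_directed
  mdu: as_directed
mealExpression:
  with each meal: 3
  with every meal: 3
  with meals: 3
  after meals: 3
  before meals: 3
  after each meal: 3
  with food: 3
  after food: 3
  before food: 3
  with or after food: 3
  at mealtimes: 3
  with breakfast: 1
  after breakfast: 1
  before breakfast: 1
  with lunch: 1
  at lunchtime: 1
  with dinner: 1
  with evening meal: 1
  at teatime: 1
  at teattime: 1
  teatime: 1
  teattime: 1
timeOfDay:
  morning: morning
  mornings: morning
  morn: morning
  mane: morning
  night: night
  nights: night
  nocte: night
  evening: evening
  bedtime: bedtime
  noon: noon
  midday: noon
  afternoon: afternoon
  in the morning: morning
  every morning: morning
  at night: night
  every night: night
  at bedtime: bedtime
  in the evening: evening
  at noon: noon
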