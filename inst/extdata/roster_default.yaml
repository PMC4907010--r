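# Reference ED capacity configuration: 19 beds; nurse counts per clock-time
# band. Band ends are inclusive to the minute; the 23:00 band wraps past
# midnight. Friday and Saturday nights draw the weekend roster via the
# shift logic.
bed_capacity: 19
nurse_bands:
  - {day_class: weekday, start: "07:00", end: "11:59", nurses: 7}
  - {day_class: weekday, start: "12:00", end: "19:59", nurses: 8}
  - {day_class: weekday, start: "20:00", end: "22:59", nurses: 7}
  - {day_class: weekday, start: "23:00", end: "06:59", nurses: 4}
  - {day_class: weekend, start: "07:00", end: "10:59", nurses: 7}
  - {day_class: weekend, start: "11:00", end: "19:59", nurses: 8}
  - {day_class: weekend, start: "20:00", end: "22:59", nurses: 7}
  - {day_class: weekend, start: "23:00", end: "06:59", nurses: 5}
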