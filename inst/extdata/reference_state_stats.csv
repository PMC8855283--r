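state,quantity,total_time_s
main,125487,1745286
task BP,48935,1253924
task weight,33560,746268
task drug,26509,600104
ranking,7856,154468
knowledge content,7330,615430
BP history,6070,185240
knowledge list,4871,100995
task food,4159,149164
questionnaire,4128,31579
health report,4055,53730
reminder item,3287,52493
appointment,3209,19157
weight history,3150,52218
reminder,2434,8426
drug history,2286,28309
show appointment,1606,261371
task uncomfortable,1345,23474
person information,1267,7779
monthly report,1144,39590
knowledge collect,1065,6094
knowledge list by tag,742,10129
BP guidance,721,19772
setting,207,1451
food history,174,3391
account,125,2110
log-in,113,2575
register,20,639
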