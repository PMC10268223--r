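{"hr":{"class":"num_cncpt","description":"heart rate","category":"vitals","unit":["bpm","/min"],"min":0,"max":300,"omopid":4239408,"target":"ts_tbl","sources":{"mimic":[{"table":"chartevents","sub_var":"itemid","ids":[211,220045],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50295],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50296],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50297],"class":"sel_itm"}],"miiv":[{"table":"chartevents","sub_var":"itemid","ids":[211,220045],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[211,220045],"class":"sel_itm"}],"wide_relative":[{"table":"vitalperiodic","class":"col_itm","value_column":"heartrate"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[6640],"class":"sel_itm"}]}},"map":{"class":"num_cncpt","description":"mean arterial pressure","category":"vitals","unit":["mmHg","mm Hg"],"min":0,"max":250,"omopid":4239021,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50299],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50300],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50301],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50302],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50303],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[220052],"class":"sel_itm"}],"wide_relative":[{"table":"vitalperiodic","class":"col_itm","value_column":"map"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[6642],"class":"sel_itm"}]}},"sbp":{"class":"num_cncpt","description":"systolic blood pressure","category":"vitals","unit":["mmHg"],"min":0,"max":300,"omopid":4152194,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50304],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50305],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50306],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50307],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50308],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90066],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90066"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90066],"class":"sel_itm"}]}},"dbp":{"class":"num_cncpt","description":"diastolic blood pressure","category":"vitals","unit":["mmHg"],"min":0,"max":200,"omopid":4154790,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50309],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50310],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50311],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50312],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50313],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90067],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90067"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90067],"class":"sel_itm"}]}},"temp":{"class":"num_cncpt","description":"body temperature","category":"vitals","unit":["C"],"min":30,"max":45,"omopid":4302666,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50314],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50315],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50316],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50317],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50318],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90068],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90068"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90068],"class":"sel_itm"}]}},"etco2":{"class":"num_cncpt","description":"end-tidal carbon dioxide","category":"vitals","unit":["mmHg"],"min":0,"max":150,"target":"ts_tbl","sources":{"eicu":[{"table":"events","sub_var":"itemid","ids":[50319],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50320],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50321],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90069],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90069"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90069],"class":"sel_itm"}]}}}
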