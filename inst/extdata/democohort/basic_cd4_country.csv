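"country","year","var1_prop","n"
"BRA","2002",0.8,5
"BRA","2003",0.5,2
"BRA","2004",0.25,4
"BRA","2005",0.4,5
"BRA","2006",1,5
"BRA","2007",0.3333,6
"BRA","2008",0.6,5
"BRA","2009",0.4286,7
"BRA","2010",0.5,6
"BRA","2011",0.125,8
"HTI","2002",0.6,5
"HTI","2003",0.3,10
"HTI","2004",0,4
"HTI","2005",0,3
"HTI","2006",1,2
"HTI","2007",0.2857,7
"HTI","2008",0.4286,7
"HTI","2009",0,2
"HTI","2010",0.6,5
"HTI","2011",0,1
"PER","2002",1,4
"PER","2003",0.3333,6
"PER","2004",0.5,6
"PER","2005",0.25,4
"PER","2006",0.8333,6
"PER","2007",1,3
"PER","2008",0.5,4
"PER","2009",0,3
"PER","2010",0.25,8
"PER","2011",0.4286,7
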