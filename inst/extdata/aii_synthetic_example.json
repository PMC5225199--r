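{"layers":{"y_inl_ipl":0,"y_ipl_gcl":50},"soma":{"z":[-3.626,-2.7195,-1.813,-0.9065,0,0.9065,1.813,2.7195,3.626],"x":[[0.736290703458901,0.711202206127498,0.637646453765723,0.520636149340402,0.36814535172945,0.190566056787096,4.50848026616448e-17,-0.190566056787096,-0.36814535172945,-0.520636149340402,-0.637646453765723,-0.711202206127498,-0.736290703458901,-0.711202206127498,-0.637646453765723,-0.520636149340402,-0.368145351729451,-0.190566056787097,-1.35254407984934e-16,0.190566056787096,0.36814535172945,0.520636149340402,0.637646453765723,0.711202206127498],[2.50884829154734,2.42336135904678,2.17272635472118,1.77402363992141,1.25442414577367,0.649337719125373,1.53622651489488e-16,-0.649337719125373,-1.25442414577367,-1.77402363992141,-2.17272635472118,-2.42336135904678,-2.50884829154734,-2.42336135904678,-2.17272635472118,-1.77402363992141,-1.25442414577367,-0.649337719125375,-4.60867954468463e-16,0.649337719125372,1.25442414577367,1.77402363992141,2.17272635472118,2.42336135904678],[3.22537300168523,3.11547108174326,2.79325495613988,2.28068312134764,1.61268650084262,0.834787960395623,1.97497136128505e-16,-0.834787960395622,-1.61268650084262,-2.28068312134764,-2.79325495613988,-3.11547108174326,-3.22537300168523,-3.11547108174326,-2.79325495613988,-2.28068312134764,-1.61268650084262,-0.834787960395625,-5.92491408385516e-16,0.834787960395621,1.61268650084261,2.28068312134764,2.79325495613988,3.11547108174326],[3.58723539093826,3.46500330908543,3.10663697790714,2.53655847064482,1.79361769546913,0.92844483844061,2.19654816965032e-16,-0.928444838440609,-1.79361769546913,-2.53655847064482,-3.10663697790714,-3.46500330908543,-3.58723539093826,-3.46500330908543,-3.10663697790714,-2.53655847064482,-1.79361769546913,-0.928444838440612,-6.58964450895097e-16,0.928444838440608,1.79361769546913,2.53655847064482,3.10663697790714,3.46500330908543],[3.7,3.57392555726955,3.20429399400242,2.61629509039023,1.85,0.957630466879328,2.2655965784226e-16,-0.957630466879326,-1.85,-2.61629509039023,-3.20429399400242,-3.57392555726955,-3.7,-3.57392555726955,-3.20429399400242,-2.61629509039023,-1.85,-0.95763046687933,-6.79678973526781e-16,0.957630466879325,1.85,2.61629509039023,3.20429399400242,3.57392555726955],[3.58723539093826,3.46500330908543,3.10663697790714,2.53655847064482,1.79361769546913,0.92844483844061,2.19654816965032e-16,-0.928444838440609,-1.79361769546913,-2.53655847064482,-3.10663697790714,-3.46500330908543,-3.58723539093826,-3.46500330908543,-3.10663697790714,-2.53655847064482,-1.79361769546913,-0.928444838440612,-6.58964450895097e-16,0.928444838440608,1.79361769546913,2.53655847064482,3.10663697790714,3.46500330908543],[3.22537300168523,3.11547108174326,2.79325495613988,2.28068312134764,1.61268650084262,0.834787960395623,1.97497136128505e-16,-0.834787960395622,-1.61268650084262,-2.28068312134764,-2.79325495613988,-3.11547108174326,-3.22537300168523,-3.11547108174326,-2.79325495613988,-2.28068312134764,-1.61268650084262,-0.834787960395625,-5.92491408385516e-16,0.834787960395621,1.61268650084261,2.28068312134764,2.79325495613988,3.11547108174326],[2.50884829154734,2.42336135904678,2.17272635472118,1.77402363992141,1.25442414577367,0.649337719125373,1.53622651489488e-16,-0.649337719125373,-1.25442414577367,-1.77402363992141,-2.17272635472118,-2.42336135904678,-2.50884829154734,-2.42336135904678,-2.17272635472118,-1.77402363992141,-1.25442414577367,-0.649337719125375,-4.60867954468463e-16,0.649337719125372,1.25442414577367,1.77402363992141,2.17272635472118,2.42336135904678],[0.736290703458901,0.711202206127498,0.637646453765723,0.520636149340402,0.36814535172945,0.190566056787096,4.50848026616448e-17,-0.190566056787096,-0.36814535172945,-0.520636149340402,-0.637646453765723,-0.711202206127498,-0.736290703458901,-0.711202206127498,-0.637646453765723,-0.520636149340402,-0.368145351729451,-0.190566056787097,-1.35254407984934e-16,0.190566056787096,0.36814535172945,0.520636149340402,0.637646453765723,0.711202206127498]],"y":[[-3,-2.8094339432129,-2.63185464827055,-2.4793638506596,-2.36235354623428,-2.2887977938725,-2.2637092965411,-2.2887977938725,-2.36235354623428,-2.4793638506596,-2.63185464827055,-2.8094339432129,-3,-3.1905660567871,-3.36814535172945,-3.5206361493404,-3.63764645376572,-3.7112022061275,-3.7362907034589,-3.7112022061275,-3.63764645376572,-3.5206361493404,-3.36814535172945,-3.1905660567871],[-3,-2.35066228087463,-1.74557585422633,-1.22597636007859,-0.827273645278817,-0.576638640953219,-0.491151708452661,-0.576638640953219,-0.827273645278817,-1.22597636007859,-1.74557585422633,-2.35066228087463,-3,-3.64933771912537,-4.25442414577367,-4.77402363992141,-5.17272635472118,-5.42336135904678,-5.50884829154734,-5.42336135904678,-5.17272635472118,-4.77402363992141,-4.25442414577367,-3.64933771912537],[-3,-2.16521203960438,-1.38731349915738,-0.719316878652363,-0.206745043860121,0.11547108174326,0.225373001685232,0.11547108174326,-0.20674504386012,-0.719316878652362,-1.38731349915738,-2.16521203960438,-3,-3.83478796039562,-4.61268650084262,-5.28068312134764,-5.79325495613988,-6.11547108174326,-6.22537300168523,-6.11547108174326,-5.79325495613988,-5.28068312134764,-4.61268650084262,-3.83478796039563],[-3,-2.07155516155939,-1.20638230453087,-0.463441529355178,0.106636977907139,0.465003309085431,0.587235390938264,0.465003309085432,0.106636977907139,-0.463441529355177,-1.20638230453087,-2.07155516155939,-3,-3.92844483844061,-4.79361769546913,-5.53655847064482,-6.10663697790714,-6.46500330908543,-6.58723539093826,-6.46500330908543,-6.10663697790714,-5.53655847064482,-4.79361769546913,-3.92844483844061],[-3,-2.04236953312067,-1.15,-0.383704909609774,0.204293994002423,0.573925557269552,0.7,0.573925557269553,0.204293994002423,-0.383704909609774,-1.15,-2.04236953312067,-3,-3.95763046687933,-4.85,-5.61629509039022,-6.20429399400242,-6.57392555726955,-6.7,-6.57392555726955,-6.20429399400243,-5.61629509039023,-4.85,-3.95763046687933],[-3,-2.07155516155939,-1.20638230453087,-0.463441529355178,0.106636977907139,0.465003309085431,0.587235390938264,0.465003309085432,0.106636977907139,-0.463441529355177,-1.20638230453087,-2.07155516155939,-3,-3.92844483844061,-4.79361769546913,-5.53655847064482,-6.10663697790714,-6.46500330908543,-6.58723539093826,-6.46500330908543,-6.10663697790714,-5.53655847064482,-4.79361769546913,-3.92844483844061],[-3,-2.16521203960438,-1.38731349915738,-0.719316878652363,-0.206745043860121,0.115471081743259,0.225373001685231,0.11547108174326,-0.206745043860121,-0.719316878652363,-1.38731349915738,-2.16521203960438,-3,-3.83478796039562,-4.61268650084261,-5.28068312134764,-5.79325495613988,-6.11547108174326,-6.22537300168523,-6.11547108174326,-5.79325495613988,-5.28068312134764,-4.61268650084262,-3.83478796039563],[-3,-2.35066228087463,-1.74557585422633,-1.22597636007859,-0.827273645278817,-0.576638640953219,-0.491151708452661,-0.576638640953219,-0.827273645278817,-1.22597636007859,-1.74557585422633,-2.35066228087463,-3,-3.64933771912537,-4.25442414577367,-4.77402363992141,-5.17272635472118,-5.42336135904678,-5.50884829154734,-5.42336135904678,-5.17272635472118,-4.77402363992141,-4.25442414577367,-3.64933771912537],[-3,-2.8094339432129,-2.63185464827055,-2.4793638506596,-2.36235354623428,-2.2887977938725,-2.2637092965411,-2.2887977938725,-2.36235354623428,-2.4793638506596,-2.63185464827055,-2.8094339432129,-3,-3.1905660567871,-3.36814535172945,-3.5206361493404,-3.63764645376572,-3.7112022061275,-3.7362907034589,-3.7112022061275,-3.63764645376572,-3.5206361493404,-3.36814535172945,-3.1905660567871]]}}
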